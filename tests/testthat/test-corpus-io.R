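test_that("filter_tokens keeps lexical tokens, drops punctuation-only entries", {
  expect_equal(filter_tokens(c("临床", "研究", "，", "。")),
               c("临床", "研究"))
  expect_equal(filter_tokens(c("a", " ", "…", "b")), c("a", "b"))
  # mixed tokens survive because they contain a lexical character
  expect_equal(filter_tokens(c("a.", "!!", "3")), c("a.", "3"))
  expect_error(filter_tokens(c("，", "。", "！")),
               class = "entroread_no_lexical_content")
})

test_that("filter_tokens is idempotent and honours extra punctuation / drop lists", {
  toks <- c("alpha", "-", "beta2", "、", "x y")
  once <- filter_tokens(toks)
  expect_identical(filter_tokens(once), once)
  # numerals retained by default, removable via drop
  expect_true("3" %in% filter_tokens(c("3", "a")))
  expect_identical(filter_tokens(c("3", "a"), drop = "3"), "a")
  # a character promoted to punctuation removes tokens made only of it
  expect_identical(filter_tokens(c("xx", "a"), extra_punct = "x"), "a")
})

test_that("build_frequency_table counts multiplicities exactly", {
  ft <- build_frequency_table(c("a", "b", "a"))
  expect_equal(ft$token, c("a", "b"))
  expect_equal(ft$count, c(2L, 1L))
  expect_equal(sum(ft$count), 3L)
  expect_equal(ft$prob, c(2 / 3, 1 / 3))

  single <- build_frequency_table("x")
  expect_equal(nrow(single), 1L)
  expect_equal(single$prob, 1)

  degen <- build_frequency_table(rep("w", 1000))
  expect_equal(nrow(degen), 1L)
  expect_equal(degen$prob, 1)
  expect_equal(sum(degen$count), 1000L)

  expect_error(build_frequency_table(character(0)), "empty")
})

test_that("frequency tables add under sequence concatenation", {
  withr::with_seed(7, {
    a <- sample(letters[1:6], 40, replace = TRUE)
    b <- sample(letters[3:9], 60, replace = TRUE)
  })
  fa <- build_frequency_table(a)
  fb <- build_frequency_table(b)
  fab <- build_frequency_table(c(a, b))
  merged <- merge(as.data.frame(fa)[, 1:2], as.data.frame(fb)[, 1:2],
                  by = "token", all = TRUE)
  merged[is.na(merged)] <- 0
  merged <- merged[order(merged$token), ]
  got <- as.data.frame(fab)[order(fab$token), c("token", "count")]
  expect_equal(got$count, as.integer(merged$count.x + merged$count.y))
  expect_equal(got$token, merged$token)
})

test_that("frequency table TSV round trip reproduces counts exactly", {
  ft <- build_frequency_table(c("apple", "pear", "apple", "plum", "pear", "apple"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_table(ft, path)
  back <- read_frequency_table(path)
  expect_equal(back$token, ft$token)
  expect_equal(back$count, ft$count)
  expect_equal(back$prob, ft$prob)
})

test_that("read_corpus resolves groups, pairs and sections from a manifest", {
  dir <- withr::local_tempdir()
  writeLines(c("the", "trial", "involves", "the", "drug"),
             file.path(dir, "m1.txt"))
  writeLines(rep(c("the", "trial", "protocol", "risk"), 3),
             file.path(dir, "g1.txt"))
  writeLines(c("section\tstart\tend", "introduction\t1\t2", "procedures\t3\t5"),
             file.path(dir, "m1.sec.tsv"))
  writeLines(paste("doc_id", "path", "group", "pair_id", "section_file",
                   sep = "\t"),
             file.path(dir, "manifest.tsv"))
  cat("m1\tm1.txt\tminor\tp1\tm1.sec.tsv\ng1\tg1.txt\tguardian\tp1\t\n",
      file = file.path(dir, "manifest.tsv"), append = TRUE)
  corpus <- read_corpus(file.path(dir, "manifest.tsv"), require_pairs = TRUE)
  expect_equal(nrow(corpus), 2L)
  expect_equal(corpus$n_tokens, c(5L, 12L))
  expect_equal(corpus$sections[[1]]$section, c("introduction", "procedures"))
  expect_null(corpus$sections[[2]])
})

test_that("read_corpus reports missing files, duplicate ids and broken pairs", {
  dir <- withr::local_tempdir()
  writeLines("a b c", file.path(dir, "d1.txt"))
  man <- file.path(dir, "manifest.tsv")

  writeLines(c("doc_id\tpath\tgroup\tpair_id",
               "d1\td1.txt\tminor\tp1",
               "d2\tabsent.txt\tguardian\tp1"), man)
  expect_error(read_corpus(man), "absent.txt")

  writeLines(c("doc_id\tpath\tgroup\tpair_id",
               "d1\td1.txt\tminor\tp1",
               "d1\td1.txt\tguardian\tp1"), man)
  expect_error(read_corpus(man), "duplicate doc_id")

  writeLines(c("doc_id\tpath\tgroup\tpair_id",
               "d1\td1.txt\tminor\tp1"), man)
  expect_error(read_corpus(man, require_pairs = TRUE), "p1")

  writeLines(c("doc_id\tpath\tgroup\tpair_id",
               "d1\td1.txt\tclassroom\tp1"), man)
  expect_error(read_corpus(man), "unknown group")
})

test_that("a generated corpus round-trips through the manifest layout", {
  corpus <- tiny_paired_corpus(n_pairs = 2, sections = TRUE)
  dir <- withr::local_tempdir()
  man <- write_corpus(corpus, dir)
  back <- read_corpus(man, require_pairs = TRUE)
  expect_equal(back$doc_id, corpus$doc_id)
  expect_equal(back$group, corpus$group)
  expect_equal(back$tokens, corpus$tokens)
  expect_equal(back$sections[[1]], corpus$sections[[1]])
})
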