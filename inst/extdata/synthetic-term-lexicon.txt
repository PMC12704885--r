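tt001
tt002
tt003
tt004
tt005
tt006
tt007
tt008
tt009
tt010
tt011
tt012
tt013
tt014
tt015
tt016
tt017
tt018
tt019
tt020
tt021
tt022
tt023
tt024
tt025
tt026
tt027
tt028
tt029
tt030
tt031
tt032
tt033
tt034
tt035
tt036
tt037
tt038
tt039
tt040
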