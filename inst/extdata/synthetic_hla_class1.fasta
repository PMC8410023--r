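>A*01:01 synthetic class I exon2-3 stand-in
VDWQIAAHCRNDTCCDCPRHQYIIQTPRHQNQNILRRVPKWPRQQKQDPFCDARGLIGHPRAYCKENYTVTNAMDYPCSQDRNFIRRCYDTIHSDTSWHEVWQWMWHRYRYNIDLAEWFEEFIHTAAGVLTQAYQSQPWREWQVYSVCSYVEYKGPQGYYACMAMMCLGQLYCPYWYRPEEF
>A*02:01 synthetic class I exon2-3 stand-in
VDWQIAAHCRNDTCCDCPRHQYIIQTPRHQNQNILYRVPPWSRQQKQDPFCDARGLIGHPRAYCKNNYTVTNAMDYPCSQDRNFIRRCYDTIHSDTSWHEVWQWMWHRYRYNIDLAEWFEEFIHTAAGFLTPANQSQPWREAQDYSVCSYVEYKGPQGYYVCMAMNCLGQLYCPTWYRPEEF
>A*03:01 synthetic class I exon2-3 stand-in
VLAVIAAHCRNDTCADCPRHQYIIQTPRTQNQNILRRVPKWPRQQKQDMFCDAKGLIGHPRAYCKENYTVTNAMDVPCSQDRRFIRRCYDTIHSDTSWHEVWQKRWHRYRYNIDLASWSEAFCHTAAGVLTEAYQSQPWREWQARSVLSYVEYDGPQKYYACGAMMCLGFLYCPYSQRPEEF
>B*01:01 synthetic class I exon2-3 stand-in
PMELVISHCQQVPQWYIASLHNNYIGEVMADHQPSAKLWFNNFLFDELARSRVMIPGYSGCWFVGWWATGYLQNYIMPYWVPFQWYAQGEPLGFVWNPLTFTFNSHVCERAKENGPDKPTPLADLEFIKVKLYSREMWYLGIIYSEWSEFKSKWIGSDDSAINYKMGRPIYMSTWWSGWPRS
>B*02:01 synthetic class I exon2-3 stand-in
PMELVISHCQQVPQFYIANLHNNYIGEVMADHQPSAKLWFNNFLFDEGARSRVMIPGYSGCWFVGWWATGYLQNYIMPYWVPFQWYAQGEPHHFPWNPLTFTFNSHVCERAKENGPDKPTPLADEEFIKVKLYSREMWYLGIIYSEWSEFKSKWIGLDDSAINYKMGEPIISSTRWSGWPRS
>B*03:01 synthetic class I exon2-3 stand-in
PMELVISHGWGVEQWYDASLHNNYIGEVMADHQPSASLWYNNFLFDELARGPVMIGGYSGCWFVGWVATGYLQNYIMPIWVPFQWYAQGEPLGFVWNPLTFTFNCHECERALQNGPDKPEPLIDLEFIKQKLPSREMWMLGIIYSEWSEFKVKWIGSDDSAINYKMGRPITMSRRWSGWPRS
>C*01:01 synthetic class I exon2-3 stand-in
CHDIVASKMWHPWVFPSMLPTWYDYMFKYCNVVYQCYVPLIETPMAHITAMISDQSGPADHVHEDHVAWKRAVMMYSSETPSNNCGVPGCPPIIGMIRVREVYYPGWKIGRPLQPSGQEWNKMCINVSNMMISSLGQMKDLPRTVEKHFKPCVLEFSFDAAITNSNGTDQQASMPKPTCWID
>C*02:01 synthetic class I exon2-3 stand-in
CHDIVASKMWHPWVFPSMLPWWYDYMFKYCNVVYQCYVPLIETPMAHITAMISDQSGPADHVHEDHVAWKRAVGMYSSETPSNNCGVPQHPPIIWKIRSREVYYPGWKIGRPLQPSGQEENKMCINVSNMMISSLGQMKDLPRTVEKHFKPCVLEFSFDAAITNYNGTHQQASMPKPTEEID
>C*03:01 synthetic class I exon2-3 stand-in
CHCIVASKMWHPWVFPSMLPFWYDYMFKYCNVVYQCGVCLIFCPCAHITAMQSFQWGPATHCHEDYVAWKRAVMMYSSKTPHNNCGVPGCPPIIGMIRVREYYYPGWKIPRPLQPSGQEWNKMCINVSNIMISSLPQMWDLPRTVEKWFKPCVLEFSFDAAIVNSNGEDQQAIMPKPTCWIQ
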