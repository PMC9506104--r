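>SYN_MCO_01
IDASKLTFSDLIGQAVKLVLVVGLEGEALDYGRLDEGTRTVFEELLMSKGCPHFKRRLHG
SYDTELPTDIFERFGPRKGYAHNHACPMGGYRRSVVNVIVAQELGGIDSDEFAVGLKAAN
TADNELETLEEPLAFLAKDVISKPYLGPILALCKRRVINL
>SYN_MCO_02
AKMAAELTTANRTNGDFMWKLSMPVSQALEEAGYSSAKPGFPSHERACQDIALLMKAAAV
LPARVFIAGGEGETFRWLAYCKCQDKQVLLIVSIEGIYQPTDWSRGEDIRTTAGIDQIPL
PRDPNKALFNGFPFNPDKLEKKPVQAISRQFRGNSQTTPP
>SYN_ALKB_01
YTGHGINPVREIRFSQGKEDVKSANLVSKSKWLLPYMLTRGSYADGQMDYRKMTRAPLSG
RYVKCIPGGKHNVLLIANKLVEIAELLTERHTVISGTSHEGLNESSVVVNNVRVFTFECS
KSLGSPGDELFKSIGTIRRQEFPLIEPGSKNELVRFPLCNDKKEFFNDTRTDKRAVYYSY
EIRGVLTPMD
>SYN_P450_01
SKETMSVNSDDWRNSRTSTEAGKLHAQEGAPNEQESNSRLQAILGVSYAVRQYELEKDIL
ERGLALYTEPFPSAYLIRKKFSVEVLTCTMTPEIGGQPGFGKGPHDIDRLLKVIFVYYLH
LTLFLRNPIKHIDKVMHKNVRIFLELPKFCLVKGGEGYGNPQTTANRYIWIAPEFTSSSA
NERSFITARVFTGGHTGILTTRDASYAVSI
>SYN_CUT_01
FTLDLQAGFVQSGAKRRLIPIADAPKLHCFEAIDLKVLNSDSDMASIFSGLMRAKSGRDI
LFCLLQPSEEAAPAVRMDAVYVINAYEYGQLQCIMNKLLPIGAVRCNGDATTFDFMINTD
QFDFMDAPTAFLSTLRRDSKSVNVCDKSQI
>SYN_PUE_01
LHKGLDLDYSRRRLSEASISALWSKRPELTIDFSPAKYMVRGRLFMPLWVPQFFQKRHFE
PKLAGFWMCSTFLMGQLSLEQSKLMLACASRIFAEFAACVHRFYNSANLLCTPAGAMISV
VDISLSSIASFDPEEWYTTEENKKSPKNQADLHISPEIYDAKLSRNVEAT
>SYN_PHBD_01
GGNGSPTVGNIQSLIASLCWPTLTYSTSDAYRPYWTSKPIIFNENNIRAQVNKKSLPVGM
QGDTIGERSTMDGWGDSTHLTAFDARVDEDRIEARAKEDECPSRQRFQHVPGDADRRSRS
EFQCRIRVWIDDSIIAETGEVDKLQVPTGTEPLAEEAQLKQVEAKNIRVGEDSEVLAYNS
>SYN_CARB_01
RSGGHSEHEELFKDGSPNDLNYSGLAPEIVYTEYIGIAVRLCSLDPKWLSTRATNNKGSS
RDGSFPGDLNGQVEEHGEVVDLDPKNGADYYDGACLNYAIGDEGKNGGSNPGDTGDVIGF
LGSTSNTSAEIKLFHGASIACKGRVASSKQIHLKASLNIVPGGMA
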