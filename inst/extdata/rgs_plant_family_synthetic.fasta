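>AtRGS1 organism=Arabidopsis_thaliana query=1
---YTQIDDQKEAPRIAYNQMMPMWEFNYYVHTLMEFKVMQKSSAQAAMPQFTGIYHAVCTCYLDMIGETAGFKPWTRNL
ISGSGTRKPHWYGMAFCPCNIYVSSAVRVVELREYGDHYNFKLTGRERPSSWSHTVWYGMKEIAMTNGINFDQCVWMMDD
GTHITFPRRCCGDCWEMLMGKFYEETTEISFNCSTKFVILIDKWVEVYTRGLLYWMIYYNKKTPAYGLFMFLITNYGMMG
NSRALVQKDGHVTKWSATWFKWTQFTKITEWIMWSGTDIRYPVPPSYAEDQFYGDMALIGASSACFQNAWDESPSWVGAS
FWNWNDHWLVIKREMQPQFCDSEEAAVDGWPEQGDGQLRHYDCQIVKSINCSLNPNYTDPTTAMPDVWLEYNWIIWQLYG
IWPDHHRASCNKE--KWNALVSPWYFSKMQGVSGRHQHISSYFSRCCEHFADAYVFESCMDLAT
>GmRGS2 organism=Glycine_max query=1
----DHLAWIREVLYPTFEALVYPSKHNDNTIFMLICFYKTAHEDNHMPNDVTPNNNNMPYNALKCCSANSYINDDYEDR
YCQPERIMMNDITIWKKPVAHNFPGQYSDVSIAKQAMFLNHRAGHIANVFHSMETGTGFIESRCYPEFHHSIVINTMPHF
FCQISDLIKIFNAGDIMNRAELHPVYAIGNLKSDGPGYFVQSNVHCIGVDSWSDHTGDMYSSVKDLRYWCRVEISSYAET
YKACDEQDGADSYYYGTPNCDCEPDCFMFYTYSIDCFYCTSYCDWDTMVKRQMQYIWNQTVAHNCMSVYRSTTQHMDIEQ
HNFLMHNLNHWKVISGTVAHSGWRAYIVVHFVEENKHRSDEVPYWISSICFCMDNYYTCKPENKIGWDYFNCGNTIHYAE
KWLTSNEYSTCSHKWYHNQVEVYEMEQHHYLTTYSAWSKISAIWMINSLCTHMP----------
>SynRGS3 organism=synthetic query=1
---YPQIDDQKKAPRKACNKEMPVPKINYYVYT-----------AQDEMAQF---------MYLPMTNTTAGFKIWPRNL
IVGGTTIKPHYNGPAFSMCAIYVSKEKRVHWLSMQPDSYYFREFGRKRPCSYSNTVWTGMKEEICNNGISPDFCSWMDDD
GTAITFPKRCSVMCNEMLNPKHYEETTEISFNCALKFWIAIDKWVEVYERGWLYWHGVYYPKRHAYRVFHFLITTKGMMG
GSRQLVIRGGHVTKWSQTWHEWTEATQLNRWIMWSGTDPRYPVWPSYNELQFYGDMALIGATSACFQNAWLESPSWVGAS
FWNWRDHWLVIKREMQPQFCDSVEAAVDGWPEQGCGQLRHYDYQIVRTINCSLNPNPTDPTTAMPDVWLEYDWIIWQLYG
KKIDHHRASCNKEKWKWNALVSPGQSSSMQCVSHRHQHISSMFWRCCQIFADAYVFESCWKFHT
>SynRGS4 organism=synthetic query=1
---YTPIIDLAEAPVFFYYQSMFMWEFNYDTFTLLED--------QAAMWHFQFAQGAHCTCYKDAEGEKAGVWQWTRFL
IGKSYSNQPACYLMQFCFCNVGVSDAVNVREIYEYGFYYNAKLNGFERPSSWSLTIGYGHGEWAMTYQRNFLQCVWMQDD
GTHGTKPVACCGDCWHMVMYKFYYVWHAISFRCDIKMAITIDKWYIVHSRGIISVVCWY---------FMQLITNLGVMD
NSRGSVPKSYCVHYISATWFKWHSFTKISEWAMQQQTDLRYCDPPSYARDQFTGDMALIGGMSAWFQNPWDESPSWVGAS
FWGWNDHWLVGKRVMQPQFCDSEEAAVDGWPEQGDGQLRHYDCQIVKSINCSLYPNATDPTTAMPDVWLEYNWIGWVLYG
IWPGHWRRSDNKEKMKWHADVSPWYYSHMQGVSTAEQHISSIYDRCREHYADEVVLESWMAWAF
>SynRGS5 organism=synthetic query=1
---DLQIEWQWEVPAWATNQMMRGWMWNYYIHIPMENKVQQWSSAQTPKPNYRGIKHLVCYCYLDHIGEYAGFAFWTHDP
ILGHTQMIP--------PHNEYLTSALSVVELREYGDHCTFKATGRERQDSDSHTLWWGMKIGIMTNGWFFWQCVHQMNG
GTHIQHPPRLIMRCWFYMMVKEYEET-----------VICIDMIVEDVHEELLYMVSYYCKKDYAYGCFQLLITCYGMVG
NAMDRVQNNKHVHKWHATWFKQTKVTKMLWWQTRQVVKWDYNVPPSTACDQFYGDMACISASSACFQNAWDESPSWVGAS
FWNWNDHWLVIKFEDQEQGFDSEIAAVDGWPEQNDGQLRNYDCQIIKSINCSLNPNATDPTTAMPDVWLAYNWIIKQGYG
IWPDHHRASCNKEKWKWNCLVSPFYFSLMQAVSGYCQHISSFFVCCWEEIAMAYVYQSCEYWAQ
>SynRGS6 organism=synthetic query=1
---EMTIFDQACAPRIDYGRIQPMWKIDYYCHTLMYFKAIQKASWQYAMFQFTGVYHAFDMHHLANCGVTAKFNPWMLNL
VSGMVFRDPQWYGAAHNPQIIYVSRAFRHSELRYKYKHYAF-----------SHWDWYGMKEIQMTAGINFDQCNWQYDD
FCHINRLKICCFDAHEMHMVKQYPMTFERSFNCVTKMVALIDMW------ELAFWMICTPKVTPAEGLGAFVQIMYGMMG
ASFAITQKEVHKTKNSATWFLSTQWTHITKWNMISNTDSRYPSPPSRVEGQFYGDMALIGASSACFQNAWDESPSWVGMS
FWNWNDSYLTIKREVLPQFCDSEEAAVDDWTEESWGQLRHYACQHVKTIMCTLGNNYTDMTTADPMVWLWYHWIIWQLYG
AWPDQHRASCNKEKWKWNALVSPYDMCKIQGVSGRHQHISSSTIRQWENAADSQAFTSCMDFWL
>SynRGS7 organism=synthetic query=1
---YDQIYDVFRAYRMAILRMMPMWEFDYYWMTLMEFKVPQSSSYAYAMPLLTEKLHAVLTCVLDMIGELADLKPW----
----ATRKTMFYDYAFCPCIKWWSSQDEVVFIMEKGDHYNKYRDTRWRDKQTAHTHWKGMQEGADTEGINFDQCVIMMDN
GYHITFAREACWDCWEMLYTMFQYVTTTIEF--------ACDKWHRVRTLGQLAVMIYYHKKTTAYGLFKCQITNYGMMG
NSHALSQLMGHVAKWNAFWMKWTFFAIITPWGMYSGIDIRYPVPMSRAEDQFYGDMALLGAMSACLQNAWDNSPEWGKAS
FWNWNDHWLVIKREMQPQSCDSEQAAFDGAPMQGDGQLSHYDCQIVKSINCSLAPNYSDPTTAMPDVWLEYEWINWNLCG
IWPDHHRASCNKEKQKWGALVSPWYFSKFQYVSYRAPLTSSGFSCEMKHFADAYVFESCADAYE
>SynRGS8 organism=synthetic query=1
---YPQIDDQKQGERADMCQMEPMWENNYYVLTLMDFKNMATSSAHAWGPQFWGCYHAFCCCQEQKIGCSAEQPPCFRNL
YSGSKTR---------CTCTIGHSFHMKCEENMRYGDHYNFKLFHYEFPSSNLTPVETYMHPIAMANGIHAVHCVWREDG
RTHITTEMRCCYDCASDMMGKFSECTRENSFPKRP--------WVDVCCTGLPAAMRYFNKWTEAWILTMKLICPYYYWH
NIRALKQKSRHVTKWSMGGFMWTRFKKFTNWIMFSETAAQYPTNPSTVEYQFYGDDALIGASSACVNTAWDESPSWVGSS
FYQWNDHWLVVIREMQFAMCDSEEAAADGWPEQGPGQLRHYDCQIVKSINCSLNPNYTDPRTARPDVWLEYNWIIGILYM
IWPDNPRASCRKEKWKWNALVSPWQFSDMMGVSGWHQHDSSYYDPKCEDYADAYKFASCMRLAR
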