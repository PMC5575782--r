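>hRGS2 organism=Homo_sapiens query=0
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
-----------------------------NNCNALEFHEESYGFDPTDCWESKEPWKQDTLPMRDSWHENDTLGSSLIFQ
YRKVIGIYWQFRRDMAPQGAHSQNFQVAWTHHHSWVGNSFNNQQDHWQVKADEMQPQYCDSEEAAGWGQPEQGDHMDNHC
YDQHVKSFNCSLNPNLFDPTTHMPDVWMEYNPCIWKHMGIAVDHHKADCNKEKWNTLVAWSQPNDLNERRQLGDLWNDMQ
>rRGS4 organism=Rattus_norvegicus query=0
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
-----------------------------------RNHVHINAEHLGHCHNRLACEDQRDVFKMREDSFMEIRYIYWDNC
LWYLKLEFGQFYGDMALIGAHSMFIQSAWFESPSPVAAWGWNWGDHWDVIKRQMQPQSCDSEEAAVHGCPYQGDGQLRHY
DCQIVKQHNCYDKFRPTWATTPMEDVWLEYPWIRWQYTGHWCDHHRASRNKQPWTALVGCHAPWKQQHDFPNNYVCPHHL
>hRGS5 organism=Homo_sapiens query=0
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
--------------------------------------------------MDNVPDTLIHDLYNGNEENLKGNTPFAYQI
LRMIAMSGYWFYGYMSLAGASNIQFQTAGDFSLHAVGASFWNWNFRWGVRVREMQPINLDSESAWIANWPEQNPAARRYY
DCQIVLSLNCLYNKNKDMPTMAMPYNWLEYNWIAWGLYGKWPDHHDASTNKEKWNSLVASRYAERAILMLH---------
>hRGS7 organism=Homo_sapiens query=0
MRCWHASAVPHDEDFYIKFNRPTSAPVDDLNEYMRDMFAQWCDIEIMHSQQIWARTTAPPFTNPNTSHYCENFPFLFTCI
VFGGRINSPDKSNFSQPICWNRVVPCQQGAEFQFSEQTDTIYPNYDCKHYFSYCKEEGMRIHAMIQKWNRMEWFTMTMTW
EEHAWAYNNIIKEPLDARWEHGFQGGHMTKAEPGTILKNKCYWDNPHRNYGYYQKECKCNCVTVCQSEDEPMDMFAVPMI
AHQRPWQQSTWIQWKWWKHKCLHVKLKVEICRFIRLIRPHIFHEYGAEQCYPGKLYCFRDCKMEFNTNFKDDCYQRMQVL
ACVWCCDAYQFYGDMALCGASSACFQNAADESPSWVGWSFWNWNVHALVIPREMQATFCDVKCAAVDGWPEWGDEQRRHY
DDQIIKSIGFSLAPQVTDCTTDTEDVWLLYNEISVQLYGEWPDNRAASCNKAKWNFLVCQFRAGVAVSK-----------
>hRGS10 organism=Homo_sapiens query=0
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
------------------------------------------------------------NPVMRCPKQIMWCYHNCAAV
VHKRWTMVGSIYGLKALSGASSAKFQNLWDESPSWVGASFKINNDYQTVIKREMQQQDCSSETAAVIPWPEQGDNQLRHY
DPQIHKRINCIKWLAYTDPDTHMEMAILQYNSIIWQLYGDWPDHHRWSCNMMKWNALVADVIASECKSHAPWG-------
>hRGS16 organism=Homo_sapiens query=0
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
--------------------------------------EGNGMFEEFTGYAEMNCRDYWHIQYVIDTCLQHHVDDVHSQV
AIRWIFPYVQFYGDMALIGHTVDCFNCNYLESPSWVGADHSHWNDHWLVIKREIFCPFCASEGAQVSGWNEQGDIQLRHY
ACSGVKSIRCSKNPNYVQPRRAMPDAMLMYLWDIWQLYGNQPCHHYNSRNHPEKNDLVCIHVMWQKTMDCTTVDWLLLGN
>hRGS18 organism=Homo_sapiens query=0
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
NNMIHPCIMCGLLMCCSITLKKPILSKIDYCWVLRNIQRGNRTMMMRDSPTNSVYNCGWYMIRVTSHRDRMTCYWMCPVC
HHDLLKLQTPFYPRIALTGASSACFQNAYDEQPSWVGASQHNFWQHWLVIARPFQPQRADCVEAAVPGQLEFKDGQWRHE
ICWIVTSINFALNPSYTFPTTAMPLVWLEYKWIIWGLGGILPDHKRASMNANKRNSLSYAVEETCVDTDQGMGSA-----
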