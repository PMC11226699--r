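>strain01
VPVNKKKVWVEKSLLNTFLAPRDNVLEPTDLAPTADFFINLDFLQGLCLLIYETFIKMKANVNPHINKSK
YVRCADDVLSYFFGTLQTFNVRKGVPPDTVSLKKCEGGPNLLMRDNQMLAAQIKVSTKEHDDLITGSSGQ
KECYSMAIPVCAGTYRSVLIGNVDGYILAYLEQYVADMPYNLTPASVDHTCLAPKRWSLEDSLLLSFVRA
DSRVKFPNFIGVCPFIRMARTMPTDEAKLSSMENRYSKAETKADTSPPVLCILSHLDGELG
>strain03
IPVNKKKVWVEKSLLNTYLGPRDHVLEPTDLAPTADFFLNLDLLQGLCLLIYPNFNKMKATVNPYIKKSK
YVRKADKVLSYFFGSLQTFNVRKGVPPDSVSLKKCKGGPCLLVRDNQMLAADIKVSTKEHDDLITGSSGQ
KTCYSMALPVCAGTYRSVLIGNVDGYLLAYLEQYVADMPYGLSPASVDHSCLSPKRWPLDDSLPLSFVRA
DSRVKFPNLIGVWPFIRAAKTMPADEAKISSMENRYSKSETKVDTSPPVVCIISHLDGGLG
>strain06
VPVNSKKLWVEKSLLNHFAVPRDNVLRPTDLAPVADFFINLDVLQGIYLQIYQNFDKMKETVDPHISKSK
YVRSADDVLSYFFGSLQTFNVRKSVSPETVALKKCEGGPYLLMRDNQLLTERMNVLTKEHDDLITRSSGD
ENCYSVAIPVSAGTYRGMLLGNIDGYVLAYLEQHVADMPYNLAPGSVDHTYLRPARWYLRDSLPKSFVRG
NTRIKFPSFIKVCPYTRMARTMPTDEATLSSMKNRYNKAENKAGQSHPVVCIPNHLDGEVG
>strain07
VPVNKRKLWVEQSLMNHFAVPADNALSPTELAPVADVFIQMDVLRGIYLQVYEQFDKMKETVNPHINKSK
YVKAADDVLSHFFGSIQTFNVRKSVSPETVALKKCEGGPYLLMRDNQLLTERINLFTKEHDDLIIKSSGN
EKCYSVAIPVSAGTYSGMLLQNLDGYILSYLEQHVADMQYNLAPGSVNHTYLSPARWDLDHSLPKSFIRS
YIRIKFPSFIKICPYTRMAKTMPTDEAASSSMKHRYSKAERKGGKSHPVVCIPNHLDDEVD
>strain02
VPVNKRKLWVEKSLMNHFAVPADNVLSPTDLAPVADVFIKMDVLQGIYLQVYEQFDKMKETVNPHINKSK
YVRAADDVLSYFFGLIQNFNVRKSVSPETVALKKCEGGPYLLMRDNQLLNERINVFTKEHDDLIVRSSGN
EKCYSVAIPVSAGTYRGMLLGNLDGYILAYLEQHIADMQYNLAPGSVDHTYLSPARKYLDDSLPKSFVRG
YIRIKFPSFIKICPYTRMAKTMPTDEATLSSMKNRYCKAERKGGKSHPVVCIPNHLDGEVG
>strain08
VPVDKKKAWVEASPLNHFLVPRDNMLSPTGLVPVADFFINLDFLTGICLLIWELFDKMKATVNPHLNKSK
YVRRADDVLSYFFGSLQLLNVRKGVSPETVALQKCEGGPYLLMRDNQLLTEHMNLFTKEHDDLITRLSGQ
KSCYSMAVPVSAGSYRGMLIGSVDGYLLAYIEKHVADMPYNLAPASVDHTCLAPARWTLDDRLPKSFVRG
NTRVKFPSFMKVCTYIRMARTMPAEEAKLASMKNRYSKAEHKNGQSPPLVCILSHLDAELG
>strain05
IPVDKKKAWVSTTPLSHYLVPRDNVLSPTDLVPVAEFFVNPNFLQGICLLIWELFDKMKATVNCHLDKAK
YIRRADDVLSYFFGSLQLLSVRKGVSPETVAIQRCVGGPYLQMRDNQLLTEHMNFSTKEHEDLLSRLSGQ
KKCHSMAIPVNANLYRGMLIGTVDGCLLAYLEKHLANMPYNLAPASVDHSCLAPARWTLDDRVPKSFVRG
NTRLKFPSFMKICTYIRRTRTMPTEEAKLASMKIRYSQAENKAESSPPVVCILSHLNAELG
>strain04
VAVDKKKAWVQTTPLSSYLVPRDNVLSPTDLVPVADFFIDLDILQGICSLVWELFDKMKATVNSHLNKAK
YVRRADDVLSYFFGSLQLLNVRKGVSPETIALQRCEGGPYLQMRDNQLLTEHMTFSTKEHEDLITRLSSQ
KKCYSMAIPVNAGLYRGMLIGSVDGCLLAYLEKHMADMPYMLAPVSVDHACLAPARWTLDDRVPKSFVRG
NTRVKFPSFMKVCTYIRMARTMPAEEAKLASMKIRYTKTENKAELSPPVVCILSHLHNELG
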