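>strain01
CEMPDGYGASLTPILPYDEAAQPTNLSPFGGIQLGLRVVRLAMQNSSVKEFYWLKADLKTCYKKLNTMNA
DQKRSVFSYASLMSQLLLLSLYNYGLVPAVGVGDHVQMIEEAVCEAVLPVQLLATRNAEFTVDIKEQLME
KGSYSEAGLALYVNSFTNQEVGANFFKDTKNMAFALNKLRYCMFWAQQRLPALAKANDNRIAVWVEANDF
YVIFAQSTLRGTKALSKKPATDVHYVVNIRSPPLEESINDFLLKNPDINTELLQVKAFPYECNIFPVKYE
AEFAMPAYALKKVFILVSVGLFDLFDRSLLADFPTGVKDKLINVITKTPRGFNCLAKICKQDKLHLKVKL
GTHWRAHVTQEDYVIKLDTNRKCVERYRGQYDYAKAPVKDELANDSCDARNVLIKESGGGVPTDQQSHIT
RSNSCYF
>strain03
CEMPDNYGAGLTPVLPYDAAAQPTNLSPFGGLQLGLLVVRLAMTNTSVKEFYWLKADLKTCYKKLNQMNS
DQKRSVFSYASLMSQLLLLSLYDYGLEPAVGVGDHVQMIELAACEAVLLVQLLAVRNAEATVDIKEQLME
QGSYSEAGAALYVNSFTNQEVGSNFLKDPKNMAFALNKLRYCMFWPQQRLPALAKANDNRIAVWVEANVF
YVIFAQSTLRGTKALSKKLAQEVHYQANIRNPPLEESINDFLLRDPDINTELAQVKAFPYECNIFPVKYE
ADFAMAHFALKKVFILVSVGLFDLFDRFLLADFPTGVKDKLINVSTREARGFNCLAKICKNDKLKLKVKL
GTHCRNNVTQEDYVIKLDSIRKCVERSRGQYDYAKAPVKDELANDGCDARQVLIKEPGGGVPTDQQGHIN
RNKPNYF
>strain06
CAMPDGYGAGVTPTLPYDEVIQPTNLSRFGAIHLKLRLVRLTTENISVKEFYWLKADLKTCYKKHNSMNT
DDKRSVFSFAALAAPLLLLSLYGYGLIPAVGVGDHVQMIEEAISEKVFTVQLLVVKNAEFTVDDKDELLE
KGLYSEAGMELYLNSYTGQEVGVNFFKDERNRAFTLNELRQCVFWAQQRLPALSKANDDSIAVWVDANDF
YVILVQPTLRGTKALTKKLATGVHYQAIIRSPPLEESIKDFLLRNPDIETALAQIMAFPYECSFFPVKYE
QEFVMPAYALKKVFTLVSVGLFDLLDHFLITDFPTGAKDKLVNVITKTPKGFRCLTKICKRDKLNLEVKL
RIHWRANITQEDYVVKLSTFRKCVERNRGQYDYAKVPINDELANDSCDAKSVLIKDQGGGVPTDRSGHIT
RSRSDYF
>strain07
CAMPDGYGAGLTPTLPYDEVVQPTNLSRFGGVQLKLRIVRLTTENISEKDFYWLKADLKTCYKKHNHMNG
DDKRSVFSFASLAAPLLQLSLYGYGLMPAVGIGDHVQMIEETVAEAVFTIQLLAIKNAEFTVDDREQLLE
KGLFSEAGLEFYVQSYTGQEIGWSFFKDEKNMAFTLNELRHCVFWVQQRIPALSKAHDNSIGVWVDANDF
YVILVQGTLRGSKALTKKLATGVHYHAIIRSPPLEEPIKDFLLRNPEIETALVQIMAFPYDCNFFPVKYE
QEFIMPAYGLKKMSTLVSVGLFDLLDHFLITCFSTSAKDKMINVITKTPKGFRCLTKVCKQDPLNLKDKL
RIHWRANVTQEDYIVKLSSFRKCEERNRGQHDYAKVPIKEELANDSCDFKSVLIKERGGGVPTDLWGHIT
RSKSDYE
>strain02
CAMPDGYGAGLTPTLPYDEVVQPTNLSRFGGVQLKLRMVRLTTENISEKEFYWLKADLKTCYKKHNHMNT
DDKRSVFSFASLAAPLLLLSLYGYGLIPAVGVGDHVQMIEEAVAEAAITIQLLAVKNAEFTVDDKEQLLE
KGLFSEAGLEFYVQSYTGQEVGVSFFKDEKNMAFTLNELKHCVFWVQQRIPALSKVNDNSISVWVDANDF
YVILVQGTLRGTKALTKKLATGVHYHAIIRSPPLEESIKDFLLRNPDIETALVQIMAFPYDCNFFPVKYG
QEFVMPAYALKKISTLVSVGLFDLLDHFLITCFPTSARDKLLNVITKTPKGFRCLTKVCKQDKLNLKVKL
SIHWRANVTQEDYVVKLSTFRKCEERNRGQHDYAKVPIKEELANDSCDAKSVLIKERGGGVPTDLSGHIT
RSKSDYE
>strain08
CALPDGYGATLKPTIPYDEAAQPTNLSRLGAIQLKQRWIRLSMENTSVKEFYWLKADLKMCYKKLNEMNA
DLARSVASYAALLSPLLILSVYGYGLVPAVGIGEHVQMIEEAVCEAVFTVQLLAVKSAEFTVDEKDDLLN
KGSYSEAGTKLHLNSYANQKVGATFFKDTKKMDFAFNEIRYCVFWAQQRLPKLAKANETSIGVWVEANDF
YVIFVQCNLRGTKILTEKLATDAHNKAIIKSPPLESNIDDFLLRNLDIDTALVQIMTSPYECNFFPVKYD
LEFVTPAYSLKKVFILVSVGLFDLYDHFLIADFPTGNKDTLINVITKAPKGISCLAKVCRQDKLNSKIKL
GTHWRANVTQEDYVIRLSTFRKCAERNRGQYDYAKVPIGDELANDSCDAKNVLIKEQGGGVPTDRAGHVT
RNKSSYF
>strain05
TALPDGYGNTFKPTIPYEEEAQPTNLSRLGGVQLKQRGVRLSTENTGVKEFYWLKADLKMCYHNLNQMNA
DLTRSVALYANLLSPLLILTVYGYGLVPAVGIGEHVQMIEEAVCEAIFTVQLLALKSAEFTVDEKDDLLD
KGSYSDVGAKFHLNSYANQKVGATFFKDVKKMDFAFNEIPYCVFWAQQRLAKLAKANVTSIAVWVEANDF
DIIFVQSNLRGTKILTKKLATDAHYKAIIRNPPLDENLDTFLLRQPDIDTALVQIMASPYECHFFPIKYD
QEFVMAAYSLKKVFILVGVRPFDTYDHFLIADFGTGKKSTLINVIAKAPKGIGCLAKVSRQDKDNLKILF
ATHYPANVTQEDYVVRPSTFRKCAERDRGQYVYAKVPYGDEFAKDSCDAKNVLIKEQGGGVPTDRAGQVP
ADKSSYF
>strain04
CALPDGYGSTFKPTIPYEEAAQPTHLSRLGGIQLKQRWVRLSTENTEVKEFYWLKADLKRCYHKLNQMNA
DLARSVASYASLLSPLLVLSVYGYGLAPAVGIGEHVQMIEEAICDAIFTVQLLAVKSAEFIVDEKDDLLD
KGSYSDLGAKLHLNSYANQQVGSTFFKDAKKMDFAFNQVPYCVFWAQQRLAKLAKANVSSVAVWVEANDF
YVIFCQSNVRGTTILTEKLATDAHYKAIIRSPPLEENLDDFLLRNPDNDTALVQIMASPLECNFFPIKYD
EEFVMATYSLKKVFILVPVGPFDLYDHFLIADFPTGKKSTLINVITKAPKGISCLSKVCRQDKDNLKITL
ATHYRANVTQEDYVIRLSTFRKCAERNRGQYDYARVPYGDDFAKDSCDAKNVLIKEQSGGVPTDRAGHVP
ANKTSYF
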