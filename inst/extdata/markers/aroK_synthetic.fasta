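>strain01
SAAGYPTLEARDLAGLHFVNRVMTANGGDLKMMESHMANLGVEAFTCIKALRCRTSPIKRIQKLEPGSIV
PNDGKNEMNCRHIWIEATLGSWERGLIAAGRNQEQIVPSGAKSVGREAIGASLPKRVEDAGVVHKEGPWK
SWNDYWLLKFSAMLADVADVSNSGHRFKLLTA
>strain03
SAAGSPSLDARDLAFLHLINRVLSANGGDLKMLESHMADLGVEAFTCIKALRCRASPIKRIQKLEPGRIV
PNNGKNVMNTRYIWVFATLDSWERGLIAASRNLEQIVPASAKSVGREAIGASLPKKVEQAGVVHKEGPWK
QWNDYWLIKFSATLADVADVSNSSHRFKLLTA
>strain06
SGARYRTLDGRELATLNFVNRVISTNGGELKTFEPHMTNLNVEAYICIKALACKSDPIKRIQKLEPGSII
PNDAKNEMNCRYIWIEAKLGSWARGLIKAERNQTHIVPGGAKSVGRAAIGASLPKRVEETGVLRKDGPWL
TFNEYWLIRFSAMLADVADVLNGSHRFKLLIA
>strain07
SGARYRTLDGRELATLNFVNRVISANGEELKTFEQHMTNLNVEAYVCIKAIRCKSDPIKRLQKLEPGNIL
PNNAHNEMNCRYIWIEAELGSWAAGLIATERDRTHIAPGGATSVGRAAIGAYSPKRVQETGVLRKDGPWL
TFSEYWLVRFAAMLADVPDVLTGTHFFKLLVA
>strain02
SGARYRTLDGRELATLNFVNRVIAANGEELKTFEQHMTNLNVEAYVCIKAIRCKSDPIKRLQKLEPSSII
PNDAHNEMNCRYIWIEAELGSWAAGIIAAERNRTHIAPGGAKSVERAAVGASLPKRVEETGVLRKDGPWL
TFNEYWLIRLAAMLADVADLLTGSHFFKLLVA
>strain08
SAGGYSNLEGRELAESNFINRVINANGGDLKMIEPHMADLNVETFTCIKALRCKADPIRRIQKLEPGSIV
PNDAKNEMNCRYIWIDAKLGSWVHGVIVAGRNQTQIVPGGVRSVGRESIGASLPKRVEETQVIRKDGQWI
TWNDYWLIRFPAPLSDLADVLNTSHRYKLLTA
>strain05
SSAGYRNLEGRELGESNFINRVINANGGDLKMTEPHMADLNLETFTCIKTLRCKAEPIRKIEKLELGSIV
AQDAKNKMNCRYIWIEKNLSSWVQGVVVAGRNQTQIVPGGVQSTGREAISASLPKRIEETQTIRKDGQWI
AWDDSWLIRFLTPLSDLADTLHNSHRHTLLLA
>strain04
SSAGYRNLAGRELGESNFINRVINANLGDLKMIEPHMADLNMDTFTCIKTLRCKADPIRRIEKLELGSII
ENDAKNEMNCRWIWIEANLCSWVRGVIVAGRTQTQVVPGGVQSVGREAISASLPKRVEETQVIHKAGKWI
AWNDSWLIRFLAPLSDLADALHNSHRYSLLLA
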