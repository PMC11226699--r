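>strain01
STLVPDEQAMEQRCELMRLERLDFGKVRGINGRGEVASRECARGRFRDNPNPLGEIVYRHGIVYLCLSGD
SENAGLQSITIDIEIQLNNEDNPYSLPIRAKFYKRNEVRLRRKIATVYSKNPLVIWTHLNDGVFYGSKML
SLIELIYDPIVYMDAFDLDLVPLQKLLQPFIVGHTCKIVEQKNMEKLHFCEDKIKHHNKDKYARSKVGGR
GELRMEDKDPCSVVSEIILLETGNIADKKMQDIEIRSNKEMRRPEMSKFVSSFGGMSQERVGSLELVFLL
YSNAETKGPRNDECTSTPDFMNHRGTHPALLDFLLNFMNTIILLDTLRTQKTLTWYRYDVMKAKGMLPMA
ESSTGPFMSNAE
>strain03
STLVPDEQAMEQRRELMRLERLDLGKVRGINGRGDVASRECSRGRFRGNPNPLGEIVYLHGVVYLRLSGE
SENADVLSVSIDIEAQLNNEGNPYALPIRAKFYKRNEVRLRRKIATVYSKNPLVIWTHLNDGVFYGSKML
SLMELIYEPVVYMDAFDIDLVPLQKLLEPFIVRHTCKAVSQKNHETLHFCEDKIKKHNKDKYARSKVSGR
GELRMEDKDPLSVVSEIILLEDGNLADKKMQDIEIPNNKEMRKPEMCKFVSTFGGMSQERVGTLEMVFLL
YSNAETKGPRNDECTSTPDFKNHRGTHPALLDFLLNFMDTIILADTLRTQRSVTWYRYDLMKAKGMLPMA
ESSTGPFLSDAE
>strain06
NSLVPEESPVVQRCEIMRLERLDLGKVRGISGRGEITSRECARGRFQDNANILGEIVYLHGLTYLCLTGG
SENAGLRSVTIDFEIQLNNEDNPYSISIRTKFYKSNEERLRRKIATVYSKNPLIIWTHLNAGVFYGSKIL
SLMELIYEPNVYMDTFDFTLVPLQKLLQPFIVRHTCTIVGQKNNQELHFCEDKIKHHNKDKYARSKPGGR
GELGMQDKDPLSVVSEIQLLEDGNIADKKMQDAPITNNNEMRRPDDTKFLTSFGGMTHARVGVLYLAFLL
YSNAESKGPRNEECTNTPYFINGRGMHPALLDFLLDFMNTIIVLDTLRTKRSLTWYRYDVMKAKGMLPMA
ESSSGPFMNNAE
>strain07
NSLVPEESPVVQRCEIMRLERLDLGKIRGISGHGEITSRECARGRFQDHDNILGEVVYHHGLTYLCATGG
SENAGFRTVTIDIEIQLNQEDNPYTISIKTQMYKSDEERLKRKVANVYSNNPLLIRTHLNLGVFYGSKIL
ALMELIYEPDVYMDSFDFALVQFQRLLQPFVVRRTCTIVGRRNTQELHFCEDKIKHINKDKYAQDKSGGR
GELGMRDKDPLSVLSEIQPLEDDNIADKEMQEAPITNNNEMCRPEDTKFVISLGAMTHVRVGVLSSAFLL
YSNAESKGPRNEECTNTPHFINGHGMHPALLDFLLDFVNTFVVLDKLRTKRSLTWYQYDVMKAKSVLPMA
ASSSGPFMSGSE
>strain02
NSLVPEDSPVVQRCEIMRLERLDLRKIRGISGRGEITSRECARGRFQDHDNILGEIVFLHGLTYLCATGG
AENAGLRTVTIDIEIQHNQEDNPYTISIKTKFYKSDEERLKRKVATVYSRNPLLIRTHLNKGVFYGSKIL
ALMELVYEPNVYMDSFDFTLVPFQRLLQPFVVRHTCTIAGRKNTQELHFCEDKIKHINKDGYARDKSGGR
GELGMQDKDPLSLVSEIQLLEDDNIADKEMQEAPITNNNEICRPEDTKFVTSFGGMTHVRVGVLPLAFQL
YSNAESKGPRNEECTNTPHFINGRGMHPALLDFLLDFMNTIVMLDTLRTKRSLTWYHYDVMKAKSMLPMA
ESSSGPFMSNSE
>strain08
SALVPDEQAAVQRCELMRLERLDLGKVRDINGRGEITSRGCARGRFQDGPNHLGEIVILHNLVYLCLSGG
SENAGLRSVSIDIEIQLNNEANPYSIPLREKLHKKNEARLGRKISTVFSKNPLLVWAHLNDEVFYGSKML
RLMELVYEPIVYMDNFDFDIWPLQKLLQPFIVRHTCMIIGQKNTEKLHFCADKIKHHNKDKYARSKNGGR
GELRMQDRDPRGVVSEIQLMEDGNVADKKMKDISITNNNDMRRPEMGKFVTSFSGMTHERVGTLDLVFLR
YSNAKTKGPRNDECTNTPHFINGRGTHPALLEFLVDFMNTIIVLDTLRTKRALSWYRYDVMRTKGMLSMA
ESNSGPFLSNAE
>strain05
NALAPDEQAAVQRFELMRLERLDVGKVRDINGKGKITSRGCARGRFQDSPNHLAEIVILHDVVYLCLAGG
SESEGLRSDSIDIEIQLGNNDNPYGVPLREQFHKENEAGLRGKITTVFSKNPLLVWAHLNGEVFFGSKML
RLVEFMYEPIVYIDNFDFDIVPIQRLLQPFTVRQSCKIIGQKNTEKLHFCEDKFKHMNKDEYARSTNGTR
GELKMQDSAPRGVVSEVELMEDGNIADHKMRDIAIRSNNSMRRPEMGKFIVSFGGMTHERVGTLDLAFLR
YSNAKTKGPRDDECINTPNFINGRGTHPALLEFLVDFMNTIIVLDTLQTKRSLTWYRYDVMKARGILSAA
ESKSGPFLSCAE
>strain04
SALIPDEQAAVQRFELMRLEGLDLGKVRDIGGRGEITSRGCSRGRFQDGPNYLGEIVILHDVVYLFLARG
SDSAGLRSVSIDIEIQLNNEDNQYAVPLREKFHNKNEAGLRRKITTVFSKNLLLVWAHLGGEVFFGSKML
RLVELVYEPIVYIDNFDFEIVPLQKLLQPFIVGQTCKIIGQKNTEKLHFCEDKIKHHNKDEYARSTSGGR
GQLRMQDSDPRGVVIDVQLMEDGNIADQKMRDIAIQSNNDMRRPEMGKFLTSFGGMTHERVGTLDLAFLR
YSNAKTKGPKNDECTPTPHFINGDGTHPAVLEFLVDFMNTILILDNLQTKRTLTWYRYDVLKAKGMLSAA
ESKSGPFLSHAE
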