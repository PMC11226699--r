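>strain01
LTWRYTPRPAINKIVGESAIARGLELNGREVYNVVMDKRDESDNATYQFLEGVLHFCRSTQLNRKEGLAC
LGEAAVLEEIRRQVRHAKDSVVFTNLRNVHCDRPVQAGPDTLGLDHATIGEINKPGTDWFRHALHSVEQP
DVTPLQGEDYRHSKIVLDTCKRYIEEKSEGQQLDGINDNLQFASLDGKERIYVIQGSFFAEELPGDDQDL
TNAEIITKGQCKYGAVMVRENGMDDTEATTFFCMMQNNYLLYPTLQKYTLQGTGDRAALFEACNEAYGSF
TTVQFGKLRWVTDIQDFCAKLRKTAYLSVLHVTGNVKVGKESNLSGILIETGLQVGFPQRKRLVTPNVWL
HTIVA
>strain03
ITWRYTHRPAINKIVGESAIARGMELNGREVYNVVMDKRDETDNATYPFLEGVLHFCRSPELKRKDGLAC
LGETAVLTEIWRQVRHARDSVVFKNLRNGHCDHSVQAGPDTLGLDHAKIGEINKPGTDWFRHALTSVEQP
EVSQLQGEDYRHSKLVLDSCKRYIDEKSEGQHLDGINDNLQFASLDAKERIYVIVSSFFAEELPGDDQDL
TNAEIITKGQCKYGPVMVRDNGMDDMSATTFFCLIQNNYLLFPALQKYTLQGTGDRKSLFEACIEAYGSF
TVVQFGKLKWVTDIQDFCTKFRKTEFLSVINVTGGVKVGKESNLTGILLEAGLQVGFPQRRRLVTPEVWM
HAIVA
>strain06
ISWRYPQKPAIARIVGESAIARGLDLDGREVYNVLMDKKEDTDNAAYQFLEGVLHFCRNAQLSRKEGVPC
LAEAVVLSEICRHVSQAKDSVVFTNLPNGYCDKPVQAGPDGSGLDHLTLGDINKPGTEITRHALHRVEQP
DVAPLQGEDYRMSEVMLDTCKRYTDEKSEGQHPDGVDDALQFSSLDGSESIYVIQGPFIAEELPRYDQDL
TTGEVITKGQCKYGAVMVRKNGMDDAQATPFFSVMRNNYLLYPALGKYTLQGTGDRASLFEACNQAYGSF
TTLSFGKLRWVTDIQHLATKLRKTAFLTVILFTGNLKVVKESNLSGILIETRLQVEFPPRKRNVTPNTWL
SAIVL
>strain07
ISWRYPQKPAIARIVGESAIARGLDLNGREVYGVLMDKKEETDNVTFQFLEKVLHFCHGAQLNRREGVPC
LADAVVLSQICRHVSQAKDSVVFTNLPNGHCDKPVHAGPEGLGLDHLMLGDITKPGTEIFQHALHSGEQP
GVAPLQGEDYRMSEVMLDACKRYTEEKSEGQHPADVDDALQFSSLDGKESIFVIAGPFIAEELPRYDQDL
TTGEVITKGQCKFGGIMVRNNGMDDAQAVPFFSRMRNNYLLYPALGRYGLQGSGDRTKSFEACNLQYGSF
TTLTFVKLRWVTDIQDLATKLRKTAFMTAILFTGNLKVVKESNLSGALIETRLQVEFPPRKDLVTPNTWI
SAIVL
>strain02
ISWRYPQKPAIARIVGESAMARGLDLNGREVYGVLMDKKEETDNVTYQFLEKVLHFCHNAQLNRKEGVPC
LADAVVLSEICRHVSQAKDSVVFTNLTNGHCDKPVHEGPDGLGLDHLMLGEITKPGTEIFQHALHSGEQP
GVAPLQGEDYRMSEVLLDACKRYTEEKSEGQHPAGTDEALQFSSLDGKESIYVIQGPFIAEELPRYDQDL
TTGEAITKGQCKYGAVMVRNNGMDDAQAAPFFSVMRNNYLLYPALGKYTLQGTGDRTKSFEACNLQYGSF
TTLTFAKLRWVTDIQDLATKLRKTAFMTVILFTGNLKVVKQSNLSGALIETRLQVEFPPRKDLVTPNTWL
SAIVI
>strain08
LTWPYTQKPAINKIVGDSAISRGSDLNGRSVYNLLMDKAEETDNANYQFLESVLYFCRSAQLNRKEGVAC
LGEPVVLTKLRRYVSHAKDSAAFTSLPNGHCDRPVQAGPDTLGLEHATLGDINKPGTEWFRSALHSLEQP
DVAPLQGEDFRLSEVVLDTCKRYIDEKSDGQHLDGENDNLQFASLDGRERIYVIKSSFFVEKLPGYDQDL
SNAEVITKGQCKYAAVMVRENGMDDAHATTFFGLLRNNYLLYPPLQKYSLQGTGDRASLFEACNDAYGSF
TTLCFGKLRWVTDIQDFATKLRKMVFLTVILVAGNIKVVKESNLSGIQIETRLKVGFPPRKGLVSPNVWP
HAIVA
>strain05
LTWPYTQKPVLQKIVGDGTIARGLDLNGRSVYNLLMDKAEETDNANFQFLESVLYFCFSAPLTRKEGEAC
LGQPVVLTKVRRYVSHAKDLVGFTNLPTGHCDRPVQAGPESLGLEHATLGGVRKPTGEWFKSVLYNLEQP
DVGPLQGKMCRLSEVAIDTCKRYLDEKSDGQHLDGETDNLQFASLDGRERVCLIKSSYFVEKLPGFDEDL
DNAEVITMGQCKYGAVMLRENGMDDSQALTFFGLMRNNYLLYAPLQKYSLKGTRERASLFEACREAYGSF
TTLCFGKLHWVTEVQDFTTKLVKMAFLTAILIADCIRVVRESNLSGIQIQTRLRVGFSPRKGLVTPNLWL
HAILA
>strain04
LTWPYTQKPVSNKIVGEAAIARGLDLNGRSVYNLLMDKSEEHDNANFQFLESVLYFCHSAKLTRKEGAAC
LGQPVALTNLRRYVSHAKDGVAFTNLPNGHCDRPVQARPDSLGLEHASLGDENKPATEWFKSALHNLEQP
DVAPLQGEDFRLSEVVIDTCKRYIDEKSDGQHLDGENDNLQFASLDGRERVCLIKSSFFAKKLPGFDQDL
NNAEVITMGQCKYGAVMLRENGMDDSQAITFFGLMRNNYLLYPPLQKYSLQGTGDRASLFEACKDAYGSF
TTFCFGKLRWVTDIQDFTTKLIKLAFATAILVADTIKVVKESNLSGLQIETRLRVGFSPRKGLVTPDVWL
HTILA
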