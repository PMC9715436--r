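>mol-miR156a species=Moringa_oleifera synthetic_standin=true
GUACUCGACUAAAUAUUAUCG
>mol-miR159a species=Moringa_oleifera synthetic_standin=true
GCUUCACUGGUUCCGCCACCU
>mol-miR159c species=Moringa_oleifera synthetic_standin=true
CGCUGCAUGCGGACGUUGUAC
>mol-miR160h species=Moringa_oleifera synthetic_standin=true
GCUGGACCAAGGUAAAUCCAU
>mol-miR162a species=Moringa_oleifera synthetic_standin=true
CAGAACACGUGGUUCCGGAAC
>mol-miR166i species=Moringa_oleifera synthetic_standin=true
UACACCCUCGAUGGCGAUUAA
>mol-miR167-5p species=Moringa_oleifera synthetic_standin=true
GGAACGUUUACAGGACAACUA
>mol-miR171a species=Moringa_oleifera synthetic_standin=true
GCACAAAACGCUGGAGCGGAC
>mol-miR393 species=Moringa_oleifera synthetic_standin=true
AAGGAACCUCAAUUCAAUCGU
>mol-miR395a species=Moringa_oleifera synthetic_standin=true
ACGAUUAGAGAAUUAGGCCCG
>mol-miR396c species=Moringa_oleifera synthetic_standin=true
GAAGAACGGUUGACUUAUUAA
>mol-miR397 species=Moringa_oleifera synthetic_standin=true
AAGCGGUGCCCUGGCGUUGAA
>mol-miR398 species=Moringa_oleifera synthetic_standin=true
GACUUCCAGUCUUUUCAGAUU
>mol-miR482b species=Moringa_oleifera synthetic_standin=true
GAGAGCUGAGGCGCAUCAGAG
>mol-miR858a species=Moringa_oleifera synthetic_standin=true
UGCACGAGAAUUUGACUCACC
>mol-miR858b species=Moringa_oleifera synthetic_standin=true
UCAGACGGGUUAUGGGGCGUG
>mol-miR2118a species=Moringa_oleifera synthetic_standin=true
UGCUGAAGAUCAGAUAACAAU
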