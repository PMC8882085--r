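{"gyrA":{"gene":"gyrA","amplicon_P1":[40,111],"amplicon_P2":[290,330],"amplicon_P3":[1230,1301],"ptt_site":300,"cleavage_site":310,"full_length":1500,"target_3prime_distance":200,"distance_tolerance_nt":25},"samT":{"gene":"samT","amplicon_P1":[40,111],"amplicon_P2":[290,330],"amplicon_P3":[1230,1301],"ptt_site":300,"cleavage_site":310,"full_length":1500,"target_3prime_distance":200,"distance_tolerance_nt":25},"metIC":{"gene":"metIC","amplicon_P1":[40,111],"amplicon_P2":[290,330],"amplicon_P3":[1230,1301],"ptt_site":300,"cleavage_site":310,"full_length":1500,"target_3prime_distance":200,"distance_tolerance_nt":25},"metE":{"gene":"metE","amplicon_P1":[40,111],"amplicon_P2":[290,330],"amplicon_P3":[1230,1301],"ptt_site":300,"cleavage_site":310,"full_length":1500,"target_3prime_distance":200,"distance_tolerance_nt":25},"mtnKA":{"gene":"mtnKA","amplicon_P1":[40,111],"amplicon_P2":[290,330],"amplicon_P3":[1230,1301],"ptt_site":300,"cleavage_site":310,"full_length":1500,"target_3prime_distance":200,"distance_tolerance_nt":25}}
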