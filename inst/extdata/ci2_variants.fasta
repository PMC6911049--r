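>ci2_wt CI2 wild type
MDLKTEWPELVGKSVEEAKKVILQDKPEAQIIVLPVGTIVTMEYRIDRVRLFVDKLDNIAEVPRVG
>ci2_eng engineered fold-switch variant
MDAKTEWPELVGKSLEEAKKALLQDKPEATIIVIPVGTIVTMEYRVDRVRIVVDKLDNIAEVPTVG
>ci2_eng_i59a engineered variant with gatekeeper truncation
MDAKTEWPELVGKSLEEAKKALLQDKPEATIIVIPVGTIVTMEYRVDRVRIVVDKLDNAAEVPTVG
>ci2_1_58 C-terminal strand truncation
MDLKTEWPELVGKSVEEAKKVILQDKPEAQIIVLPVGTIVTMEYRIDRVRLFVDKLDN
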