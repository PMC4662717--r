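sample_id,prescription_no,sho
Keishi-To,1,Deficiency
Keishi-ka-ogi-To,2,Deficiency
Keishi-ka-kakkon-To,3,Deficiency
Keishi-ka-kei-To,4,Deficiency
Keishi-ka-koboku-kyonin-To,5,Deficiency
Keishi-ka-shakuyaku-To,6,Deficiency
Keishi-ka-shakuyaku-daio-To,7,Excess
Keishi-ka-shakyaku-shokyo-ninjin-To,8,Deficiency
Keishi-ka-ryukotsu-borei-To,9,Deficiency
Keishi-ni-eppi-Itto,10,Excess
Keishi-ni-mao-Itto,11,Deficiency
Keishi-mao-kakuhan-To,12,Middle
I-rei-To,13,Middle
Kakkon-To,14,Excess
Kakkon-To-ka-senkyu-shin-i,15,Excess
Kakkon-ka-hange-To,16,Excess
Goshaku-San,17,Deficiency
Saiko-keishi-To,18,Deficiency
Keishi-kanzo-To,19,Deficiency
Keishi-kyo-kei-ka-bukuryo-To,20,Deficiency
Keishi-kyo-shakuyaku-To,21,Deficiency
Keishi-ninjin-To,22,Deficiency
Keishi-bukuryo-Gan,23,Excess
Ogi-keishi-gomotsu-To,24,Deficiency
Ogon-To,25,Excess
Ogon-ka-hange-shokyo-To,26,Excess
Kikyo-To,27,Middle
Sai-kan-To,28,Excess
Sho-saiko-To,29,Excess
Sho-saiko-To-ka-kikyo-sekko,30,Excess
Shokyo-shashin-To,31,Deficiency
Dai-saiko-To,32,Excess
Toki-shigyaku-To,33,Deficiency
Toki-shigyaku-ka-goshuyu-shokyo-To,34,Deficiency
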