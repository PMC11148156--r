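>enz01
ATMMKDFCKRKSFVYMYRIKCPHWRWKLTDGFFKCLMMPSEWEVLMKHMNPRHQDDNKSS
>enz02
AQMRKDSCKRMGFVYMWRIKCSNKRWIRLKRFHKCLMWPSEWEVLMKGHNPRHQDDNKQQ
>enz03
AQMMMLSCKIKGFVYMWRIKCSDKRWITLDRFHKCLMWPSEWEVLHYGYNPHHQDCNRYQ
>enz04
AQMPKDSCKNYFMKTILRCGCSHKSNIDGERMHQCFMHGHEWHCIDTMHNIVHQDNAKQF
>enz05
AQMPKDSVKNYVMKTILRCSCSHKSNIDGDRYEQCHMIGSWWYCWDMMHNPVHQDPAKQM
>enz06
LQMPKMSCKNYFMKTILRCWCSHKSNIDGERMHQPHMIGSEWHCLDTMHNPVHGDPAKFM
>enz07
WCDPKTKCKRCVFIHISRCFCSNKPNIQGELMNDCYMITSEWYILDSGLFPVHTCPYGHM
>enz08
WQMPNTKCKRCGFTHISRCTCSNEPNIQGDFMNKCHMILIEWYILDSGKFPVATYPYGQG
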