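enzyme,chavicol_like,eugenol_like,dimethoxy_like,amine_like
enz01,4.792568247857582,3.830067086634876,9.459888250923541,9.996404380875395
enz02,33.382630811596059,32.744008256306564,43.651769282814307,70.455990679089567
enz03,12.173297658347876,9.045634700979619,15.068541378801362,9.541918295302716
enz04,0.877688973061024,0.562305253218643,1.448073347678947,0.744296592023715
enz05,3.066302694273912,1.971801275274242,2.440883897460389,1.756053445925201
enz06,0.874014245407308,1.033179347465542,0.729011893512089,0.847822972524972
enz07,1.838455509641161,2.518359581748405,2.926149103957484,5.232122895682770
enz08,11.834992211526957,9.461448231627557,9.653867475565750,22.478032967198711
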