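feature,layer,depth_zone,metric,value
grooves,superficial,shallow,mu_s,39.56
grooves,superficial,mesophotic,mu_s,52.92
spines,superficial,shallow,g,0.87
spines,superficial,mesophotic,g,0.83
grooves,superficial,shallow,g,0.96
grooves,volumetric,shallow,g,0.70
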