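# Inputs for estimating rural/urban female adult mortality (45q15) from the
# national female rate: under-five mortality ratios relative to the urban
# reference and population shares, circa 2010.
# national_female_q45_15=0.2739
name,rank,pop_share,u5_ratio
rural,1,0.832,1.373
urban,2,0.168,1.0
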