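location_id,t_uav_s,t_ambulance_s
L1-2,210,300
L3-4,240,360
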