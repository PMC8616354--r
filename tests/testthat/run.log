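platemorph run | config hash b00c7fea08024066b3f6a56365f1c497 | seed 1
config: {"stages":"segment","input":"x.tif","pixel_size":1,"frame_interval":10,"seed":1,"min_area":0,"rolling_ball_radius":50,"threshold":"otsu","gate":20,"smooth_sigma":1,"min_filopodium_length":0.5,"min_tip_curvature":2}
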