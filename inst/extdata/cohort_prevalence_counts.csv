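measure,n_prc_with,n_noprc_with,total
early_prc,351,0,125740
nadir_low,111,17895,125740
median_low,61,18207,125740
duration_high,73,13335,125740
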