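sample_id	donor_id	replicate_id	subset_label	sorted_cell_count
HD01_CD27pos_r1	HD01	r1	CD27pos	50000
HD01_CD27pos_r2	HD01	r2	CD27pos	50000
HD02_CD27pos_r1	HD02	r1	CD27pos	50000
HD02_CD27pos_r2	HD02	r2	CD27pos	50000
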