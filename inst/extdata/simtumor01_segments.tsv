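chrom	start	end	major_cn	minor_cn	segment_id
chr1	1000000	60999495	1	1	seg001
chr2	1000000	41029989	3	2	seg002
chr3	1000000	23841552	1	1	seg003
chr4	1000000	28651486	2	1	seg004
chr5	1000000	51761381	2	2	seg005
chr6	1000000	22718801	4	2	seg006
chr7	1000000	24282646	2	2	seg007
chr8	1000000	44179251	4	2	seg008
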