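sample_id	segment_id	major_cn	minor_cn	bp	route_id	n_events	n_gains	gain_times	gain_phases	gain_times_param	t_w	wgd	purity	reads_per_clonal_copy
simtumor01	seg001	1	1	59999496	x(1)|x(1)	3	0				0.523041365528479	TRUE	0.75	12
simtumor01	seg002	3	2	40029990	p(p(x(1),x(1)),x(1))|p(x(1),x(1))	9	3	0.271849,0.455450,0.507565	pre,pre,pre	0.2718492371,0.5075646555,0.4554496259	0.523041365528479	TRUE	0.75	12
simtumor01	seg003	1	1	22841553	x(1)|x(1)	3	0				0.523041365528479	TRUE	0.75	12
simtumor01	seg004	2	1	27651487	w(1,1)|x(1)	2	0				0.523041365528479	TRUE	0.75	12
simtumor01	seg005	2	2	50761382	w(1,1)|w(1,1)	1	0				0.523041365528479	TRUE	0.75	12
simtumor01	seg006	4	2	21718802	p(x(1),x(q(1,q(1,1))))|p(x(1),x(1))	9	4	0.080476,0.419019,0.738457,0.822853	pre,pre,post,post	0.0804759286,0.7384568912,0.8228531280,0.4190188193	0.523041365528479	TRUE	0.75	12
simtumor01	seg007	2	2	23282647	w(1,1)|x(q(1,1))	3	1	0.648612	post	0.6486116789	0.523041365528479	TRUE	0.75	12
simtumor01	seg008	4	2	43179252	x(q(1,q(1,q(1,1))))|x(q(1,1))	7	4	0.633607,0.758363,0.845408,0.867104	post,post,post,post	0.6336072771,0.8454084368,0.8671037190,0.7583629596	0.523041365528479	TRUE	0.75	12
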