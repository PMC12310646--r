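label	n_events	n_reports
nae_among_all_reports	3999	170053
deaths_among_nae	946	3999
cemiplimab_nae_share	60	1959
avelumab_nae_share	66	2165
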