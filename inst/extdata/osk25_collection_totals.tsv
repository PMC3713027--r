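key	value
distinct_nodes	16664
nodes_in_single_gil	6608
summed_edges	282484
edges_in_single_gil	201121
meta_network_edges	13578
meta_network_within_gil_edges	12253
meta_network_cross_gil_edges	1325
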