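t_ms	x_px	y_px	hit	target_index
967.230849918112	285.816206008146	243.34288087141	TRUE	1
2089.43199605322	528.446112909477	715.898753343414	FALSE	2
2389.43199605322	550.097500053872	692.217760263853	TRUE	2
2901.98440421825	705.206269028019	235.503032582228	TRUE	3
3556.33846521789	289.108812355602	645.874277705314	FALSE	4
3856.33846521789	277.531314113516	676.725551205167	FALSE	4
4156.33846521789	304.365993102687	670.200171546556	FALSE	4
4456.33846521789	297.144580802954	690.177454657445	TRUE	4
5049.01683102071	89.7449269666321	697.959608404018	TRUE	5
5815.86145847879	122.293200571997	241.59970093679	TRUE	6
6443.06895860724	707.209755859904	546.155934656774	TRUE	7
6954.03986067899	719.59218833302	372.376291998941	TRUE	8
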