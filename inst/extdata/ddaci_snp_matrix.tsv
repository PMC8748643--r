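variant	1762	2546	6408	6607	6912	7306	7869	8640	10276	11033
Bfra485	C	A	G	G	T	C	T	G	A	A
Bn171	T	C	C	A	C	G				
Bn240	.	.	.	A	G	.	.	C	.	C
Bn342							A			
Bt194					A					
Bt210									G	
Zst503							A			
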