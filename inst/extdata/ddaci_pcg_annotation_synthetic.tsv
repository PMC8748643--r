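symbol	start	end	strand	class
cox1	1500	3035	+	PCG
nad5	6300	8018	-	PCG
nad4	8601	9938	-	PCG
cob	10150	11283	+	PCG
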