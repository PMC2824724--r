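category	feeding_larva	spinning_larva	pupa	moth	total
non-codingRNAs (rRNA, tRNAs etc.,)	558345	167369	94118	169508	989340
conserved and novel miRNAs	43278	70143	67256	69913	250590
messenger RNAs	101508	27736	9577	13564	152385
mitochondrial RNAs	7356	951	231	201	8739
repetitive elements	147327	40034	16522	30965	234848
subtotal	832966	293424	182808	272612	1581810
cannot be mapped to the available genome	314787	305855	106495	191188	918325
Total	1147753	599279	289303	463800	2500135
Unique small RNAs	350095	245339	101669	150197	739119
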