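reference_set	library	redundant	unique	references_mapped	references_total
genome	normal	1696901	121147	14704	60119
genome	cold	287434	93924	15407	60119
genome	salt	1246244	299703	30565	60119
genome	light	1279786	199655	18707	60119
genome	Total	4510365	584976	36241	60119
cds	normal	845384	62727	9081	31895
cds	cold	100461	47494	10409	31895
cds	salt	409316	161005	20890	31895
cds	light	407496	100456	12916	31895
cds	Total	1762657	314399	24143	31895
est	normal	1001210	58952	5523	15003
est	cold	116588	38342	5730	15003
est	salt	561687	98136	8922	15003
est	light	623155	97314	7844	15003
est	Total	2302640	225734	10582	15003
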