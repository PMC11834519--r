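# code	role	dimension	scale	name
E-Input1	input	Economy	monetary	Center's self-raised Annual Construction Costs
E-Input2	input	Economy	monetary	Center's Self-raised Annual Operating Costs
E-Input3	input	Efficiency	count	Number of Employees in CCFs
E-Input4	input	Effectiveness	count	Number of Service Functions
E-Output1	output	Economy	monetary	Profitability
E-Output2	output	Efficiency	count	Annual Number of Services Completed
E-Output3	output	Effectiveness	rating	Older People Satisfaction with Service Experience
E-Output4	output	Equity	rating	Equity in Service Delivery
E-Output5	output	Equity	rating	Complaint Status
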