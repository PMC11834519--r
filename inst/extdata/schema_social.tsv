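# code	role	dimension	scale	name
S-input1	input	Economy	monetary	Construction Costs Subsidized by the Government
S-input2	input	Economy	monetary	Annual Operating Subsidies Received from Government
S-input3	input	Efficiency	count	Number of Employees in CCFs
S-input4	input	Effectiveness	count	Number of Service Functions
S-output1	output	Economy	monetary	Profitability
S-output2	output	Efficiency	count	Number of Rehired Laid-off Workers
S-output3	output	Efficiency	count	Annual Number of Services Completed
S-output4	output	Efficiency	ratio	Community Service Coverage Rate
S-output5	output	Effectiveness	rating	Older People Satisfaction with Service Experience
S-output6	output	Effectiveness	count	Number of Older People with Improved Quality of Life
S-output7	output	Equity	rating	Equity in Service Delivery
S-output8	output	Equity	rating	Complaint Status
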