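RULE R1:  => COPE:LackOfPhysicalActivity leadsTo DO:Obesity
RULE R2:  => HIO:%ObesityPrevalence isHealthIndicatorFor DO:Obesity
RULE R3:  => DO:Obesity isRiskFactorOf DO:Diabetes
RULE RB1: ?p livesIn ?t & ?t has ?m & ?m isA ?mc & ?mc measures ?rf => ?p isExposedTo ?rf
RULE RB2: ?p isExposedTo ?rf & ?rf leadsTo ?d => ?p atRiskOf ?d
RULE RB3: ?p atRiskOf ?d & ?d isRiskFactorOf ?d2 => ?p shouldBeScreenedFor ?d2
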