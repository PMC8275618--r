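# Synthetic reconstruction of state-level tiger census counts (2010/2014/2018)
# assembled from publicly available All-India Tiger Estimation figures.
# 18 states/regions harboring tiger reserves; Goa and Nagaland excluded for
# incomplete data. Not a transcription of any study's supplementary tables.
unit_id,count_t0,count_t1,count_t2
Andhra Pradesh,45,46,48
Arunachal Pradesh,24,28,29
Assam,143,167,190
Bihar,8,28,31
Chhattisgarh,26,46,19
Jharkhand,10,3,5
Karnataka,300,406,524
Kerala,71,136,190
Madhya Pradesh,257,308,526
Maharashtra,169,190,312
Mizoram,5,3,0
Odisha,32,28,28
Rajasthan,36,45,69
Sunderbans,70,76,88
Tamil Nadu,163,229,264
Telangana,27,22,26
Uttar Pradesh,118,117,173
Uttarakhand,227,340,442
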