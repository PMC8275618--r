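# Synthetic reconstruction of state-level attributes for the tiger study.
# landscape_class: 1 = Shivalik-Gangetic plain, 2 = Central India & Eastern
# Ghats, 3 = Western Ghats, 4 = North-East hills & Sundarbans.
# reserve_count: tiger reserves notified by 2018 (public NTCA listing).
# reserve_count_interval_1/2: reserves added in 2010-2014 / 2014-2018.
# core_area_interval_1/2: average % increase in reserve core area per interval.
# temp_anomaly_t0/t1/t2 (deg C) and precip_anomaly_t0/t1/t2 (% of normal
# departure) at the 2010/2014/2018 census years: plausible synthetic values,
# not measured records.
unit_id,landscape_class,reserve_count,reserve_count_interval_1,reserve_count_interval_2,core_area_interval_1,core_area_interval_2,temp_anomaly_t0,temp_anomaly_t1,temp_anomaly_t2,precip_anomaly_t0,precip_anomaly_t1,precip_anomaly_t2
Andhra Pradesh,2,1,0,0,2,1,0.8,0.5,0.4,5,-8,-12
Arunachal Pradesh,4,3,0,1,5,12,0.6,0.4,0.3,-3,-15,-6
Assam,4,4,0,1,3,10,0.7,0.4,0.3,-8,-20,-15
Bihar,1,1,0,0,0,2,1.0,0.6,0.5,2,-10,-18
Chhattisgarh,2,3,0,0,4,1,0.9,0.5,0.4,6,-6,-4
Jharkhand,2,1,0,0,0,1,1.0,0.6,0.5,3,-12,-22
Karnataka,3,5,0,0,6,3,0.7,0.5,0.5,8,-14,5
Kerala,3,2,0,0,2,1,0.6,0.4,0.4,4,-22,14
Madhya Pradesh,2,6,0,0,8,4,1.0,0.6,0.5,5,-9,-11
Maharashtra,2,6,2,0,15,5,0.9,0.5,0.4,7,-13,-8
Mizoram,4,1,0,0,0,0,0.5,0.3,0.2,-5,-18,-24
Odisha,2,2,0,0,1,2,0.9,0.5,0.4,4,-7,-5
Rajasthan,2,3,1,0,12,4,1.1,0.7,0.6,12,-5,-14
Sunderbans,4,2,0,0,0,1,0.7,0.4,0.3,0,-11,-9
Tamil Nadu,3,4,1,0,10,3,0.8,0.6,0.5,-2,-16,-23
Telangana,2,2,2,0,18,5,0.9,0.6,0.5,6,-10,-13
Uttar Pradesh,1,3,1,0,14,3,1.0,0.6,0.5,1,-19,-2
Uttarakhand,1,2,0,1,2,11,0.9,0.5,0.4,-4,-17,-10
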