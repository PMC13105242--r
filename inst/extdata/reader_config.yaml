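# Column mapping for the Movebank-style CSVs written by make_cohort_study()
timestamp: timestamp
lat: location_lat
lon: location_long
alt: height_above_msl
bird_id: individual_local_identifier
cohort: cohort
accel_t: timestamp
accel_x: acc_x
accel_y: acc_y
accel_z: acc_z
accel_unit: ms2
gps_pattern: "*_gps.csv"
accel_pattern: "*_acc.csv"
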