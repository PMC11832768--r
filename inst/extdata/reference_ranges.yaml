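adolescent:
  HR:
    mean: 75.0
    sd: 12.0
  SBP:
    mean: 115.0
    sd: 12.0
  DBP:
    mean: 65.0
    sd: 9.0
  MBP:
    mean: 80.0
    sd: 9.0
  RR:
    mean: 15.0
    sd: 3.0
  SPO2:
    mean: 98.0
    sd: 1.5
  TEMP:
    mean: 36.8
    sd: 0.5
infant:
  HR:
    mean: 120.0
    sd: 20.0
  SBP:
    mean: 85.0
    sd: 12.0
  DBP:
    mean: 50.0
    sd: 9.0
  MBP:
    mean: 62.0
    sd: 9.0
  RR:
    mean: 30.0
    sd: 6.0
  SPO2:
    mean: 98.0
    sd: 1.5
  TEMP:
    mean: 37.0
    sd: 0.5
newborn:
  HR:
    mean: 140.0
    sd: 20.0
  SBP:
    mean: 70.0
    sd: 10.0
  DBP:
    mean: 40.0
    sd: 8.0
  MBP:
    mean: 50.0
    sd: 8.0
  RR:
    mean: 45.0
    sd: 8.0
  SPO2:
    mean: 97.5
    sd: 1.5
  TEMP:
    mean: 37.0
    sd: 0.5
preschool:
  HR:
    mean: 110.0
    sd: 15.0
  SBP:
    mean: 95.0
    sd: 12.0
  DBP:
    mean: 55.0
    sd: 9.0
  MBP:
    mean: 68.0
    sd: 9.0
  RR:
    mean: 24.0
    sd: 5.0
  SPO2:
    mean: 98.0
    sd: 1.5
  TEMP:
    mean: 36.8
    sd: 0.5
school:
  HR:
    mean: 95.0
    sd: 15.0
  SBP:
    mean: 100.0
    sd: 12.0
  DBP:
    mean: 60.0
    sd: 9.0
  MBP:
    mean: 73.0
    sd: 9.0
  RR:
    mean: 20.0
    sd: 4.0
  SPO2:
    mean: 98.0
    sd: 1.5
  TEMP:
    mean: 36.8
    sd: 0.5
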