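bird_id,date,time,lon,lat,lat_status,filters,retained
fixture,2012-02-22,2012-02-22 12:00:00,2,40,ok,,TRUE
fixture,2012-02-23,2012-02-23 12:00:00,2.2,40,ok,,TRUE
fixture,2012-02-24,2012-02-24 12:00:00,2.4,40,ok,,TRUE
fixture,2012-02-25,2012-02-25 12:00:00,2.6,40,ok,,TRUE
fixture,2012-02-26,2012-02-26 12:00:00,2.8,55,ok,,TRUE
fixture,2012-02-27,2012-02-27 12:00:00,3,40,ok,,TRUE
fixture,2012-02-28,2012-02-28 12:00:00,3.2,40,ok,,TRUE
fixture,2012-02-29,2012-02-29 12:00:00,3.4,40,ok,,TRUE
fixture,2012-03-01,2012-03-01 12:00:00,3.6,29.5,ok,,TRUE
fixture,2012-03-02,2012-03-02 12:00:00,3.8,40,ok,,TRUE
fixture,2012-03-03,2012-03-03 12:00:00,4,40,ok,,TRUE
fixture,2012-03-04,2012-03-04 12:00:00,4.2,40,ok,,TRUE
fixture,2012-03-05,2012-03-05 12:00:00,20,40,ok,,TRUE
fixture,2012-03-06,2012-03-06 12:00:00,4.6,40,ok,,TRUE
fixture,2012-03-07,2012-03-07 12:00:00,4.8,40,ok,,TRUE
fixture,2012-03-08,2012-03-08 12:00:00,5,40,ok,,TRUE
fixture,2012-03-09,2012-03-09 12:00:00,5.2,40,ok,,TRUE
fixture,2012-03-10,2012-03-10 12:00:00,5.4,40,ok,,TRUE
fixture,2012-03-11,2012-03-11 12:00:00,5.6,40,ok,,TRUE
fixture,2012-03-12,2012-03-12 12:00:00,5.8,40,ok,,TRUE
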