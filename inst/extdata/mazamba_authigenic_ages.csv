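sample_id,context,s1_n0_1e8,s1_n0_sigma_1e8,s1_age_ma,s1_age_sigma_ma,s2_n0_1e8,s2_n0_sigma_1e8,s2_age_ma,s2_age_sigma_ma,s3_n0_1e8,s3_n0_sigma_1e8,s3_age_ma,s3_age_sigma_ma
Be18-Gor-GPL1NE-1,fluvio-deltaic,1.3867,0.0521,8.591,0.179,0.640,0.034,7.043,0.190,0.226,0.007,4.958,0.165
Be18-Gor-GPL1NE-2,fluvio-deltaic,1.3867,0.0521,14.568,0.268,0.640,0.034,13.020,0.273,0.226,0.007,10.935,0.252
Be18-Gor-GPL1NE-3,estuarine-lagoonal,0.640,0.034,8.957,0.199,0.640,0.034,8.957,0.199,0.226,0.007,6.872,0.173
Be18-Gor-GPL1NE-4,estuarine-lagoonal,0.640,0.034,14.540,0.519,0.640,0.034,14.540,0.519,0.226,0.007,12.455,0.508
Be18-Gor-GPL1NE-5,estuarine-lagoonal,0.640,0.034,17.779,0.696,0.640,0.034,17.779,0.696,0.226,0.007,15.693,0.687
Be18-Gor-GPL1NE-6,estuarine-lagoonal,0.640,0.034,6.870,0.227,0.640,0.034,6.870,0.227,0.226,0.007,4.785,0.206
17-Gor-GPL2-5,estuarine-lagoonal,0.640,0.034,8.940,0.186,0.640,0.034,8.940,0.187,0.226,0.007,6.855,0.158
17-Gor-GPL2-10,estuarine-lagoonal,0.640,0.034,7.778,0.201,0.640,0.034,7.778,0.201,0.226,0.007,5.692,0.176
17-Gor-GPL6-3,estuarine-lagoonal,0.640,0.034,10.952,0.225,0.640,0.034,10.952,0.225,0.226,0.007,8.866,0.201
17-Gor-GPL6-8,estuarine-lagoonal,0.640,0.034,10.761,0.308,0.640,0.034,10.761,0.308,0.226,0.007,8.675,0.291
Be18-Gor-GPL12-0.1,fluvio-deltaic,1.3867,0.0521,17.100,0.450,0.640,0.034,15.552,0.452,0.226,0.007,13.467,0.439
Be18-Gor-GPL12-1.1,fluvio-deltaic,1.3867,0.0521,19.531,0.842,0.640,0.034,17.983,0.843,0.226,0.007,15.898,0.835
Be18-Gor-GPL12-3.1,estuarine-lagoonal,0.640,0.034,10.887,0.233,0.640,0.034,10.887,0.233,0.226,0.007,8.802,0.209
Be18-Gor-GPL12-4.1,fluvio-deltaic,1.3867,0.0521,16.894,0.570,0.640,0.034,15.346,0.572,0.226,0.007,13.261,0.562
Be18-Gor-GPL12-5.1,estuarine-lagoonal,0.640,0.034,13.159,0.288,0.640,0.034,13.159,0.288,0.226,0.007,11.073,0.268
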