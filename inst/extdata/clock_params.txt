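"name" "value" "lower" "upper" "unit" "free"
"v1" 25.8371870151223 0.05 50 "units/h" TRUE
"q1" 1.40257646736434 0 20 "units/h" TRUE
"K1" 3.34481512970264 0.01 5 "units" TRUE
"K2" 1.2866422941439 0.01 5 "units" TRUE
"K3" 0.416706364278515 0.01 5 "units" TRUE
"a1" 0.051987342142114 0 5 "1" TRUE
"K4" 1.8730739641198 0.01 5 "units" TRUE
"m1" 1.55095654285914 0.05 8 "1/h" TRUE
"m1d" 3 0 3 "1/h" TRUE
"p1" 4.62036276734694 0.05 10 "1/h" TRUE
"d1" 1.90064306980422 0.05 8 "1/h" TRUE
"v2" 11.715447336276 0.05 50 "units/h" TRUE
"q2" 8.36852207908547 0 20 "units/h" TRUE
"K5" 0.55063606173065 0.01 5 "units" TRUE
"K6" 4.04466289550144 0.01 5 "units" TRUE
"m2" 0.921023732652269 0.05 8 "1/h" TRUE
"p2" 4.61894291277805 0.05 10 "1/h" TRUE
"d2" 7.4838364405426 0.05 8 "1/h" TRUE
"v3" 25.4419892642234 0.05 50 "units/h" TRUE
"K7" 1.91636153960678 0.01 5 "units" TRUE
"K15" 0.966338758668123 0.01 5 "units" TRUE
"c3" 0.135728192697823 0 1 "1" TRUE
"K8" 0.825946608568534 0.01 5 "units" TRUE
"m3" 1.14702758329373 0.05 8 "1/h" TRUE
"p3" 1.10634402179912 0.05 10 "1/h" TRUE
"d3" 1.08384187337941 0.05 8 "1/h" TRUE
"d3z" 0 0 2 "1/(units*h)" FALSE
"v4" 3.84301104165562 0.05 50 "units/h" TRUE
"q4" 0.00137995626695439 0 20 "units/h" TRUE
"K9" 0.0315653544587413 0.01 5 "units" TRUE
"c4" 0.111939869142149 0 1 "1" TRUE
"K10" 0.867141064021249 0.01 5 "units" TRUE
"m4" 0.573539148286064 0.05 8 "1/h" TRUE
"m4l" 0.0911297099373265 0 3 "1/h" TRUE
"p4" 0.143558921021888 0.05 10 "1/h" TRUE
"d4" 1.13271577316653 0.05 8 "1/h" TRUE
"v5" 45.6287898000658 0.05 50 "units/h" TRUE
"K11" 0.0289094814180017 0.01 5 "units" TRUE
"K12" 3.28874279147221 0.01 5 "units" TRUE
"K13" 4.72740696444342 0.01 5 "units" TRUE
"m5" 6.49956834209902 0.05 8 "1/h" TRUE
"m5l" 2.71255168812111 0 3 "1/h" TRUE
"p5" 2 0.05 10 "1/h" TRUE
"d5" 0.6 0.05 8 "1/h" TRUE
"v6" 4.36469326845448 0.05 50 "units/h" TRUE
"q6" 8.27827257903551 0 20 "units/h" TRUE
"K14" 0.985035608899018 0.01 5 "units" TRUE
"m6" 0.63387918593945 0.05 8 "1/h" TRUE
"p6" 2.59829317615637 0.05 10 "1/h" TRUE
"d6" 1.29871167689637 0.05 8 "1/h" TRUE
"d6d" 0.663072486637116 0 2 "1/h" TRUE
"c_ec" 10 0.05 10 "units/h" TRUE
"K_ec" 0.0929193721211641 0.01 5 "units" TRUE
"d_ec" 0.311472429531475 0.05 5 "1/h" TRUE
"g_ec" 0 0 2 "1/(units*h)" FALSE
"c_rl" 4.39624366870394 0.05 5 "1/h" TRUE
"d_rl" 1.77539199173499 0.05 5 "1/h" TRUE
"g_zg" 0.274964430711108 0 2 "1/(units*h)" TRUE
"q_zg" 1 0 5 "1" TRUE
"r_zg" 0.137482215355554 0.01 5 "1/h" TRUE
"d_zg" 0.412446646066661 0.01 5 "1/h" TRUE
"v_zt" 0.549928861422215 0.01 5 "units/h" TRUE
"d_zt" 0.412446646066661 0.01 5 "1/h" TRUE
"v_cc" 0.549928861422215 0.01 5 "units/h" TRUE
"d_cc" 0.206223323033331 0.01 5 "1/h" TRUE
"k_cn" 0.412446646066661 0.01 5 "1/h" TRUE
"k_nd" 0.549928861422215 0.01 5 "1/h" TRUE
"k_dn" 0.549928861422215 0.01 5 "1/h" TRUE
"d_cn" 0.206223323033331 0.01 5 "1/h" TRUE
"d_cd" 0.343705538388884 0.01 5 "1/h" TRUE
"v_hy" 0.687411076777769 0.01 5 "units/h" TRUE
"d_hy" 0.343705538388884 0.01 5 "1/h" TRUE
"g_hy" 0.549928861422215 0 5 "1/(units*h)" TRUE
"s_p" 2.43764094882087 0.01 5 "1/h" TRUE
"d_p" 0.630418197686605 0.01 5 "1/h" TRUE
"v7" 14.485161959453 0.05 20 "units/h" TRUE
"K17" 0.218623505212679 0.01 5 "units" TRUE
"K18" 0.241467278931267 0.01 5 "units" TRUE
"k7" 0.0984895559137372 0.05 5 "1/h" TRUE
"p7" 0.67461049215479 0.05 5 "1/h" TRUE
"d7" 1.11905988978373 0.05 5 "1/h" TRUE
"v8" 1.14894276610738 0.05 20 "units/h" TRUE
"K19" 3.80045376339241 0.01 5 "units" TRUE
"k8" 1.55688556344905 0.05 5 "1/h" TRUE
"p8" 0.346313353868086 0.05 5 "1/h" TRUE
"d8" 0.05906459803626 0.05 5 "1/h" TRUE
"v9" 0.0646087912537074 0.05 20 "units/h" TRUE
"K20" 2.84911997361089 0.01 5 "units" TRUE
"k9" 0.0620961141617324 0.05 5 "1/h" TRUE
"p9" 1.39565961095209 0.05 5 "1/h" TRUE
"d9" 0.130096239716518 0.05 5 "1/h" TRUE
"v10" 0.0688322885710664 0.05 20 "units/h" TRUE
"K21" 3.2301652920238 0.01 5 "units" TRUE
"k10" 0.0751937187320216 0.05 5 "1/h" TRUE
"p10" 0.259122968041587 0.05 5 "1/h" TRUE
"d10" 0.363255912027457 0.05 5 "1/h" TRUE
"I_A" 0 0 0.01 "1/(umol m-2 s-1)" FALSE
"I_B" 0.583333333333333 1e-04 10 "1" FALSE
"I_C" 41.6666666666667 0 500 "umol m-2 s-1" FALSE
"hill" 2 1 4 "1" FALSE
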