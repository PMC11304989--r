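setting,n_clinical,phantom,sens_fp0.125,sens_fp0.25,sens_fp0.5,sens_fp1,sens_fp2,sens_fp4,sens_fp8,cpm_printed,ci_lo,ci_hi
basic_aug,5,0,0.468,0.557,0.623,0.662,0.717,0.756,0.789,0.653,0.037,0.125
basic_aug,5,1,0.517,0.606,0.688,0.759,0.815,0.859,0.894,0.734,NA,NA
basic_aug,25,0,0.553,0.625,0.674,0.721,0.751,0.793,0.830,0.707,0.036,0.113
basic_aug,25,1,0.569,0.665,0.746,0.813,0.863,0.891,0.910,0.780,NA,NA
basic_aug,50,0,0.578,0.668,0.726,0.778,0.814,0.853,0.875,0.756,0.032,0.088
basic_aug,50,1,0.624,0.700,0.789,0.847,0.892,0.912,0.936,0.814,NA,NA
basic_aug,100,0,0.695,0.767,0.813,0.864,0.890,0.903,0.920,0.836,-0.031,0.012
basic_aug,100,1,0.641,0.722,0.790,0.866,0.898,0.929,0.946,0.827,NA,NA
basic_aug,400,0,0.775,0.848,0.898,0.926,0.947,0.968,0.973,0.905,-0.029,-0.008
basic_aug,400,1,0.723,0.813,0.878,0.921,0.939,0.962,0.970,0.886,NA,NA
full_ssl,5,0,0.592,0.662,0.772,0.777,0.822,0.861,0.888,0.761,-0.014,0.040
full_ssl,5,1,0.574,0.658,0.742,0.800,0.849,0.884,0.903,0.773,NA,NA
full_ssl,25,0,0.640,0.716,0.786,0.830,0.864,0.899,0.910,0.806,-0.011,0.039
full_ssl,25,1,0.661,0.717,0.777,0.850,0.897,0.913,0.922,0.820,NA,NA
full_ssl,50,0,0.703,0.773,0.830,0.870,0.908,0.920,0.940,0.849,-0.035,0.009
full_ssl,50,1,0.661,0.733,0.791,0.871,0.915,0.939,0.949,0.837,NA,NA
full_ssl,100,0,0.723,0.780,0.858,0.910,0.923,0.936,0.954,0.869,-0.034,0.002
full_ssl,100,1,0.674,0.747,0.823,0.883,0.924,0.943,0.961,0.851,NA,NA
full_ssl,400,0,0.757,0.844,0.897,0.933,0.955,0.963,0.971,0.903,-0.027,0.003
full_ssl,400,1,0.730,0.814,0.871,0.920,0.951,0.965,0.971,0.889,NA,NA
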