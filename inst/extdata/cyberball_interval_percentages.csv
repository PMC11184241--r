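emotion,condition,interval1,interval2,interval3,interval4,interval5,interval6,interval7,interval8,interval9,interval10
happiness,inclusion,15.64,24.10,10.99,12.20,15.79,5.10,11.04,10.99,12.48,8.40
happiness,exclusion,12.77,14.95,15.24,20.00,13.44,14.07,21.43,27.25,22.60,32.70
sadness,inclusion,25.68,24.62,29.71,29.89,32.32,32.78,36.70,31.36,26.97,32.50
sadness,exclusion,26.77,20.26,21.90,30.00,25.79,34.54,30.80,23.92,27.29,36.79
anger,inclusion,22.78,21.76,13.92,19.49,14.84,18.69,18.36,23.61,30.77,27.05
anger,exclusion,24.15,19.96,15.71,16.19,13.41,8.86,14.29,13.37,6.70,7.11
surprise,inclusion,10.26,9.19,9.16,9.41,11.00,9.65,10.86,8.26,4.40,3.76
surprise,exclusion,5.83,15.49,15.24,12.86,13.88,21.21,8.04,13.44,19.78,20.44
fear,inclusion,4.36,5.79,1.90,2.93,1.50,1.72,1.96,0.51,0.56,7.33
fear,exclusion,4.84,2.89,6.67,4.29,3.85,2.86,3.57,3.37,5.82,0.71
disgust,inclusion,1.94,0.51,0.51,0.51,1.58,2.83,2.88,6.62,7.05,2.58
disgust,exclusion,2.38,1.47,0.48,2.86,1.90,1.90,3.57,1.47,0.00,0.00
contempt,inclusion,19.34,14.03,33.81,25.57,22.97,29.24,18.19,18.66,17.78,18.39
contempt,exclusion,23.27,24.98,24.76,13.81,27.73,16.56,18.30,17.18,17.80,2.25
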