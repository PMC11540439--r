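milestone,3rd,5th,10th,25th,Median,75th,90th,95th,97th
tPB2,2.07,2.25,2.52,2.98,3.48,3.99,4.45,4.72,4.90
tPNa,6.44,6.67,7.03,7.63,8.30,8.97,9.57,9.93,10.16
tPNf,20.99,21.29,21.74,22.50,23.34,24.18,24.94,25.39,25.68
t2,22.92,23.28,23.84,24.76,25.79,26.82,27.75,28.30,28.66
t3,33.46,33.89,34.55,35.66,36.89,38.12,39.23,39.89,40.32
t4,34.31,34.81,35.59,36.89,38.33,39.78,41.08,41.86,42.36
t5,45.28,45.87,46.77,48.27,49.94,51.62,53.12,54.02,54.61
t6,47.14,47.80,48.84,50.56,52.47,54.38,56.11,57.14,57.81
t7,49.18,49.93,51.10,53.05,55.22,57.39,59.34,60.51,61.27
t8,51.94,52.79,54.11,56.30,58.74,61.17,63.37,64.68,65.53
t9,62.47,63.42,64.89,67.34,70.06,72.78,75.22,76.69,77.64
tSC,71.79,72.85,74.47,77.18,80.20,83.21,85.93,87.55,88.61
tM,79.66,80.82,82.61,85.60,88.92,92.25,95.24,97.03,98.19
tSB,88.85,90.13,92.09,95.37,99.02,102.67,105.95,107.91,109.19
tB,98.81,100.21,102.35,105.94,109.92,113.90,117.49,119.63,121.03
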