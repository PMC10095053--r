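# dataset_id=example_synthetic
# location_id=f2_loc01
# repeat_index=1
# flow_ml_min=2
# step_um=50
depth_um,po2_mmHg
0,259.73197699428675
50,262.58750053671343
100,260.95131366972981
150,252.98308991380421
200,197.61842918989592
250,140.70992492988179
300,93.740720002315143
350,63.566308800230644
400,43.42035386212936
450,40.166767411710325
500,46.402158313264813
550,70.90966080750195
600,110.28815601658529
650,155.98949284561581
700,191.61093038839573
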