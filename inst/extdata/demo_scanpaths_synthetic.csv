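stimulus_id,subject_id,index,x,y,duration_ms
demo_image,s01,0,679.86,481.97,80.77
demo_image,s01,1,671.77,528.86,81.46
demo_image,s01,2,345.83,103.76,74.42
demo_image,s01,3,360.31,96.94,114.53
demo_image,s01,4,336.04,111.51,108.84
demo_image,s01,5,247.22,496.14,216.15
demo_image,s01,6,332.58,123.78,191.52
demo_image,s02,0,346.58,92.63,231.7
demo_image,s02,1,666.73,523.56,351.19
demo_image,s02,2,265.21,514.98,296.91
demo_image,s02,3,342.82,106.86,118.1
demo_image,s02,4,346.78,119.71,11.15
demo_image,s03,0,330.54,82.83,148.04
demo_image,s03,1,680.67,529.09,96.67
demo_image,s03,2,706.35,538.08,31.32
demo_image,s03,3,634.53,511.19,128.07
demo_image,s03,4,378.25,96.1,206.15
demo_image,s04,0,325.68,118.26,126.89
demo_image,s04,1,351.11,110.37,62.22
demo_image,s04,2,325.72,101.45,99.27
demo_image,s04,3,670.38,540.94,258.65
demo_image,s04,4,689.33,568.92,39.94
demo_image,s04,5,322.67,88.03,229.47
demo_image,s04,6,293.41,520.61,59.86
demo_image,s04,7,266.88,506.85,82.71
demo_image,s05,0,342.31,131.9,118.4
demo_image,s05,1,340.03,104.95,50.31
demo_image,s05,2,356.63,91.97,18.01
demo_image,s05,3,690.29,527.59,201.7
demo_image,s05,4,641.06,515.08,129.92
demo_image,s05,5,244.18,512.75,55.9
demo_image,s05,6,243.9,490.41,21.13
demo_image,s05,7,251.74,506.96,103.69
demo_image,s05,8,319.2,104.4,469.65
demo_image,s05,9,316.46,88,84.93
demo_image,s06,0,356.24,115.29,16.49
demo_image,s06,1,349.63,92.48,160.39
demo_image,s06,2,335.69,110.73,107.94
demo_image,s06,3,682.14,508,135.68
demo_image,s06,4,658.32,567.68,73.86
demo_image,s06,5,661.71,506.11,58.56
demo_image,s06,6,334.45,107.77,193.24
demo_image,s06,7,330.66,79.83,178.57
demo_image,s06,8,264.2,500.45,38.27
demo_image,s06,9,281.47,506.25,130.83
demo_image,s06,10,256.29,506.05,141.42
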