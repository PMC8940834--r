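metric,dose,low_dose,predicted
psnr,half,33.22,37.34
psnr,quarter,28.25,35.37
psnr,eighth,24.51,32.37
ssim,half,0.96,0.98
ssim,quarter,0.93,0.97
ssim,eighth,0.89,0.95
rmse,half,5.69,3.50
rmse,quarter,10.10,4.41
rmse,eighth,15.52,6.26
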