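tissue,rho,sigma,eps_r,k,c,omega,Q,active,k_star,omega_star
air,1.2,0,1,NA,NA,NA,NA,FALSE,NA,NA
blood,1050,NA,NA,NA,3617,NA,NA,FALSE,NA,NA
bone,1908,0.09,13.1,0.32,1312,10,0.15,TRUE,NA,NA
brainstem,1046,1.05,55.1,0.51,3630,559,11.4,TRUE,NA,NA
cartilage,1099,0.6,45.1,0.49,3568,35,0.54,TRUE,NA,NA
cerebellum,1045,1.05,55.1,0.51,3653,763,15.5,TRUE,NA,NA
cerebrum,1045,0.75,56.8,0.55,3696,763,15.5,TRUE,NA,NA
fat,911,0.08,11.6,0.21,2348,32.7,0.51,TRUE,0.5,255
lucite,1180,0.003,2.6,NA,NA,NA,NA,FALSE,NA,NA
lung,394,0.38,23.6,NA,NA,NA,NA,FALSE,NA,NA
muscle,1090,0.8,56.7,0.49,3421,39.1,0.96,TRUE,0.4,442.8
optical_nerve,1075,0.46,35,0.49,3613,160,2.5,TRUE,NA,NA
sclera,1032,1.01,57.4,0.58,4200,380,5.9,TRUE,NA,NA
spinal_cord,1005,1.53,69,0.59,4047,160,2.5,TRUE,NA,NA
tumor,1050,0.89,59,0.51,3950,72.3,0,TRUE,1.5,848
thyroid,1050,0.89,61.3,0.52,3609,5624,87,TRUE,NA,NA
vitreous_humor,1005,1.53,69,0.59,4047,0,0,TRUE,NA,NA
water,1000,0.04,78,NA,NA,NA,NA,FALSE,NA,NA
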