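predictor,response,species,adj_r2,residual_se,f_stat,p_value
guard,crop_loss,baboon,0.61,10.7,14.9,.005
camera,crop_loss,baboon,0.80,7.63,36.9,<.001
guard,events,baboon,0.45,2.29,8.49,.020
camera,events,baboon,0.90,0.99,78.6,<.001
guard,crop_loss,vervet,0.54,1.58,11.4,.010
camera,crop_loss,vervet,0.25,2.00,4.04,.079
guard,events,vervet,0.69,0.77,21.1,.002
camera,events,vervet,0.41,1.06,7.19,.028
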