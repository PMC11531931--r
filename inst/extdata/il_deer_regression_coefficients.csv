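level,covariate,estimate,lower,upper,direction,change
TRS,(Intercept),-0.084,NA,NA,NA,NA
TRS,deer_density_prev,0.724,0.684,0.765,Increase,1.063
TRS,lcu,0.344,0.306,0.382,Increase,0.411
TRS,no_hunt,0.21,0.17,0.249,Increase,0.234
TRS,public_hunt,0.075,0.032,0.116,Increase,0.078
TOWNSHIP,(Intercept),-1.772,NA,NA,NA,NA
TOWNSHIP,deer_density_prev,0.949,0.801,1.096,Increase,1.583
TOWNSHIP,lcu,0.609,0.449,0.776,Increase,0.839
TOWNSHIP,no_hunt,0.357,0.154,0.56,Increase,0.429
TOWNSHIP,public_hunt,0.192,0.007,0.388,Increase,0.212
COUNTY,(Intercept),-0.011,NA,NA,NA,NA
COUNTY,deer_density_prev,0.715,0.636,0.792,Increase,1.044
COUNTY,lcu,0.169,0.118,0.22,Increase,0.184
COUNTY,no_hunt,-0.599,-0.754,-0.444,Decrease,0.82
COUNTY,public_hunt,0.018,-0.159,0.195,NA,NA
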