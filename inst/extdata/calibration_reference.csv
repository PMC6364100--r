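compound,slope,intercept,r_squared,lod,loq,range_lo,range_hi
gigantol,632964,-95693,0.994,1,2,2,100
erianin,14667,3462,0.996,1,2,2,100
chrysotobibenzyl,718654,9443,0.994,1,2,2,100
tristin,474132,-15725,0.996,1,2,2,100
moscatin,874152,84434,0.998,1,2,2,100
confusarin,364943,38924,0.997,1,2,2,100
coumarin,14793,2938,0.995,0.5,1,1,100
naringenin,261143,-18631,0.993,0.5,1,1,100
apigenin,914992,-115674,0.999,1,2,2,100
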