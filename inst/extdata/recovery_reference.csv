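compound,sample_content,recovery_50,rsd_50,recovery_200,rsd_200
gigantol,12.7,95.8,4.3,83.2,2.3
erianin,345,93.8,4.4,97.5,7.2
chrysotobibenzyl,300,82.1,6.8,97.2,3.8
tristin,15,91.8,6.1,91.5,6.7
moscatin,,91.7,8.7,91.2,6.5
confusarin,250,93.6,6.3,89.4,6.2
coumarin,,95.4,6.2,92.7,6.3
naringenin,6.26,90.8,5.2,88.5,5.4
apigenin,125,88.6,3.6,94.2,4.7
ddb,16.7,92.5,4.2,91.5,4.3
moscatilin,220,88.7,5.3,93.8,5.4
chrysotoxin,32,97.2,3.9,91.7,5.8
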