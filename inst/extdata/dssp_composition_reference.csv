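set,ss8,count
training,H,1306610
training,G,135498
training,I,714
training,E,800297
training,B,41026
training,C,764391
training,S,331075
training,T,417815
test2017,H,233961
test2017,G,21404
test2017,I,177
test2017,E,129425
test2017,B,6793
test2017,C,133183
test2017,S,57678
test2017,T,68973
test2019,H,31854
test2019,G,2300
test2019,I,33
test2019,E,15411
test2019,B,916
test2019,C,21605
test2019,S,9804
test2019,T,9452
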