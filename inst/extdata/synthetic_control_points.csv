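"x","y","lux"
500.8,509.9,3.392
712,288.4,6.742
748.6,592.7,4.403
454.1,137.8,1.934
49.6,837.6,2.337
474.5,673.6,8.505
410.8,760,17.325
706.4,859.3,15.62
183,323.9,3.128
836.4,375.1,4.443
434.1,210.2,2
414.5,168.9,1.434
299.6,139.1,1.055
307.9,724.9,24.326
66,464.1,2.785
163.1,845,2.881
509,874.8,3.913
777.5,658,12.628
130.7,422.8,4.05
468.2,221.8,2.054
635.8,494.6,3.558
406.2,198.7,1.669
342,92.9,1.282
800.6,812.6,34.039
95,353.7,2.134
190.7,132.3,1.31
87.1,246.5,1.491
662,427.7,2.424
79,794.6,2.634
466,167.3,1.862
346.8,208.3,1.953
723.3,614.6,4.067
856,203.7,2.723
353.4,407.5,4.66
601.2,120.9,4.272
454.6,326.7,2.451
602.5,378.8,3.251
850.8,431.1,2.954
305.9,652.7,30.363
520.2,791.6,4.469
269.3,643.7,21.218
53.9,260.8,1.54
128.7,243.6,1.478
783.2,362.4,6.423
442.6,214,2.094
814.4,831.8,28.075
737.3,54.9,2.932
33,795.7,2.2
402,306.6,2.82
500.5,580.6,5.901
567.8,75.5,2.198
302.7,105.4,0.981
564.9,113.6,3.663
339.4,498.2,11.711
869.3,746.4,4.439
460.4,679.7,14.689
29.6,379.3,2.383
364.9,526.7,7.733
796.7,223.8,4.47
871.8,757.7,6.748
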