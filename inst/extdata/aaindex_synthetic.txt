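H SYNI000101
D Synthetic hydrophobicity-like scale (fixture, not a curated index)
R
A synthetic record in AAindex1 layout for offline tests
* generated values, no physical meaning
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.620  -2.530  -0.780  -0.900   0.290  -0.850  -0.740   0.480  -0.400   1.380
    1.060  -1.500   0.640   1.190   0.120  -0.180  -0.050   0.810   0.260   1.080
//
H SYNI000102
D Synthetic bulkiness-like scale (fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   11.500  14.280  12.820  11.680  13.460  14.450  13.570   3.400  13.690  21.400
   21.400  15.710  16.250  19.800  17.430   9.470  15.770  21.670  18.030  21.570
//
H SYNI000103
D Synthetic polarity-like scale (fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.000   52.000   3.380   40.700   1.480   3.530   49.910   0.000   51.600   0.130
    0.130   49.500   1.430   0.350   1.580   1.670   1.660   2.100   1.610   0.130
//
H SYNI000104
D Synthetic duplicate of SYNI000101 (identical values, must be removed)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.620  -2.530  -0.780  -0.900   0.290  -0.850  -0.740   0.480  -0.400   1.380
    1.060  -1.500   0.640   1.190   0.120  -0.180  -0.050   0.810   0.260   1.080
//
H SYNI000105
D Synthetic incomplete scale (contains NA, must be skipped)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.100      NA   0.300   0.400   0.500   0.600   0.700   0.800   0.900   1.000
    1.100   1.200   1.300      NA   1.500   1.600   1.700   1.800   1.900   2.000
//
H SYNI000106
D Synthetic flexibility-like scale (fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.357   0.529   0.463   0.511   0.346   0.493   0.497   0.544   0.323   0.462
    0.365   0.466   0.295   0.314   0.509   0.507   0.444   0.305   0.420   0.386
//
H SYNI000107
D Synthetic isoelectric-like scale (fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    6.000  10.760   5.410   2.770   5.050   5.650   3.220   5.970   7.590   6.020
    5.980   9.740   5.740   5.480   6.300   5.680   5.660   5.890   5.660   5.960
//
H SYNI000108
D Synthetic volume-like scale (fixture)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   88.600 173.400 114.100 111.100 108.500 143.800 138.400  60.100 153.200 166.700
  166.700 168.600 162.900 189.900 112.700  89.000 116.100 227.800 193.600 140.000
//
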