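H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
      3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H FASG760101
D Molecular weight (Fasman, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    89.09  174.20  132.12  133.10  121.15  146.15  147.13   75.07  155.16  131.17
   131.17  146.19  149.21  165.19  115.13  105.09  119.12  204.24  181.19  117.15
//
H ZIMJ680104
D Isoelectric point (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     6.00   10.76    5.41    2.77    5.05    5.65    3.22    5.97    7.59    6.02
     5.98    9.74    5.74    5.48    6.30    5.68    5.66    5.89    5.66    5.96
//
H FASG760104
D pK-N (pK' of the alpha-amino group, Fasman, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     9.69    9.04    8.80    9.60   10.28    9.13    9.67    9.60    9.17    9.68
     9.60    8.95    9.21    9.13   10.60    9.15    9.10    9.39    9.11    9.62
//
H FASG760105
D pK-C (pK' of the alpha-carboxyl group, Fasman, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     2.34    2.17    2.02    1.88    1.96    2.17    2.19    2.34    1.82    2.36
     2.36    2.18    2.28    1.83    1.99    2.21    2.09    2.83    2.20    2.32
//
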