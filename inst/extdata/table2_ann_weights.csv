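value
8.11
2.98
4.35
-0.08
6.15
-3.08
4.64
1.67
2.82
-7.44
13.95
1.69
-4.77
-0.41
-1.49
7.15
-1.24
-2.70
1.07
1.39
8.09
6.46
3.58
4.45
0.53
1.19
-3.80
4.81
3.62
5.60
6.54
1.38
-0.75
-0.90
-0.17
12.64
-7.44
6.17
2.07
-2.74
-1.14
5.65
3.66
-2.92
1.31
0.75
0.55
1.71
2.82
0.33
4.65
2.47
-5.69
1.22
-3.58
5.39
-3.16
3.93
1.57
2.49
3.81
4.21
4.38
3.56
7.31
-6.14
-8.06
7.90
1.53
-3.35
0.10
-0.35
-1.41
2.71
3.44
0.86
-6.30
-3.23
-5.29
-5.53
-0.78
-1.84
-6.06
5.89
-0.69
-0.03
1.57
-8.06
3.49
0.32
4.89
-6.89
-2.29
1.38
-2.76
-3.70
-4.73
-5.77
-2.44
2.96
-5.44
-1.43
-3.11
-1.19
4.10
-1.61
0.79
3.98
-1.26
-2.46
1.00
0.54
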