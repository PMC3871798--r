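g: -5.0
e: -1.0
w1: 2.0
w2: 1.0
matrices:
  R:
  - - 0.44
    - -3.64
    - -3.24
    - -1.17
    - -3.64
    - -7.72
    - -5.32
    - -7.25
    - -3.24
    - -5.32
    - -6.92
    - -4.85
    - -1.17
    - -7.25
    - -4.85
    - -6.78
  - - -3.64
    - -0.62
    - -4.26
    - -0.83
    - -7.72
    - -4.7
    - -6.34
    - -6.91
    - -7.32
    - -2.3
    - -7.94
    - -4.51
    - -5.25
    - -4.23
    - -5.87
    - -6.44
  - - -3.24
    - -4.26
    - -0.75
    - -1.52
    - -7.32
    - -8.34
    - -2.83
    - -7.6
    - -6.92
    - -5.94
    - -4.43
    - -5.2
    - -4.85
    - -7.87
    - -2.36
    - -7.13
  - - -1.17
    - -0.83
    - -1.52
    - 6.87
    - -5.25
    - -4.91
    - -0.6
    - -2.21
    - -4.85
    - 0.49
    - -5.2
    - 3.19
    - 0.22
    - -4.44
    - -0.13
    - -1.74
  - - -3.64
    - -7.72
    - -7.32
    - -5.25
    - -0.62
    - -4.7
    - -2.3
    - -4.23
    - -4.26
    - -6.34
    - -7.94
    - -5.87
    - -0.83
    - -6.91
    - -4.51
    - -6.44
  - - -7.72
    - -4.7
    - -8.34
    - -4.91
    - -4.7
    - -1.68
    - -3.32
    - -3.89
    - -8.34
    - -3.32
    - -8.96
    - -5.53
    - -4.91
    - -3.89
    - -5.53
    - -6.1
  - - -5.32
    - -6.34
    - -2.83
    - -0.6
    - -2.3
    - -3.32
    - 5.19
    - -2.58
    - -5.94
    - -1.96
    - -3.45
    - -1.22
    - 0.49
    - -5.53
    - 2.98
    - -4.79
  - - -7.25
    - -6.91
    - -7.6
    - -2.21
    - -4.23
    - -3.89
    - -2.58
    - -1.19
    - -7.87
    - -5.53
    - -8.22
    - -2.83
    - -4.44
    - -6.1
    - -4.79
    - -3.4
  - - -3.24
    - -7.32
    - -6.92
    - -4.85
    - -4.26
    - -8.34
    - -5.94
    - -7.87
    - -0.75
    - -2.83
    - -4.43
    - -2.36
    - -1.52
    - -7.6
    - -5.2
    - -7.13
  - - -5.32
    - -2.3
    - -5.94
    - 0.49
    - -6.34
    - -3.32
    - -1.96
    - -5.53
    - -2.83
    - 5.19
    - -3.45
    - 2.98
    - -0.6
    - -2.58
    - -1.22
    - -4.79
  - - -6.92
    - -7.94
    - -4.43
    - -5.2
    - -7.94
    - -8.96
    - -3.45
    - -8.22
    - -4.43
    - -3.45
    - -1.94
    - -2.71
    - -5.2
    - -8.22
    - -2.71
    - -7.48
  - - -4.85
    - -4.51
    - -5.2
    - 3.19
    - -5.87
    - -5.53
    - -1.22
    - -2.83
    - -2.36
    - 2.98
    - -2.71
    - 5.68
    - -0.13
    - -4.79
    - -0.48
    - -2.09
  - - -1.17
    - -5.25
    - -4.85
    - 0.22
    - -0.83
    - -4.91
    - 0.49
    - -4.44
    - -1.52
    - -0.6
    - -5.2
    - -0.13
    - 6.87
    - -2.21
    - 3.19
    - -1.74
  - - -7.25
    - -4.23
    - -7.87
    - -4.44
    - -6.91
    - -3.89
    - -5.53
    - -6.1
    - -7.6
    - -2.58
    - -8.22
    - -4.79
    - -2.21
    - -1.19
    - -2.83
    - -3.4
  - - -4.85
    - -5.87
    - -2.36
    - -0.13
    - -4.51
    - -5.53
    - 2.98
    - -4.79
    - -5.2
    - -1.22
    - -2.71
    - -0.48
    - 3.19
    - -2.83
    - 5.68
    - -2.09
  - - -6.78
    - -6.44
    - -7.13
    - -1.74
    - -6.44
    - -6.1
    - -4.79
    - -3.4
    - -7.13
    - -4.79
    - -7.48
    - -2.09
    - -1.74
    - -3.4
    - -2.09
    - -0.7
  D:
  - - 2.22
    - -1.86
    - -1.46
    - -1.39
  - - -1.86
    - 1.16
    - -2.48
    - -1.05
  - - -1.46
    - -2.48
    - 1.03
    - -1.74
  - - -1.39
    - -1.05
    - -1.74
    - 1.65
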