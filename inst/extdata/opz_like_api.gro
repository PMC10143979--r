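generated by dispermd
   16
    1OPZ     O1    1   2.000   2.000   2.000
    1OPZ     HO    2   1.940   2.075   2.000
    1OPZ     C1    3   2.141   2.000   2.000
    1OPZ    H1A    4   2.177   2.060   2.080
    1OPZ    H1B    5   2.177   2.060   1.920
    1OPZ     C2    6   2.251   1.895   2.000
    1OPZ     O2    7   2.306   1.786   2.000
    1OPZ      N    8   2.373   1.965   2.000
    1OPZ     HN    9   2.413   2.058   2.000
    1OPZ     C3   10   2.508   1.905   2.000
    1OPZ    H31   11   2.548   1.955   2.085
    1OPZ    H32   12   2.548   1.955   1.915
    1OPZ     C4   13   2.601   1.785   2.000
    1OPZ    H41   14   2.701   1.815   2.000
    1OPZ    H42   15   2.641   1.725   2.085
    1OPZ    H43   16   2.641   1.715   1.925
   4.00000   4.00000   4.00000
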