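synthetic microsatellite baselines (3 samples x 24 fish, 5 loci)
locus01
locus02
locus03
locus04
locus05
Pop
ind0001 ,  108108 101101 106108 106107 108104
ind0002 ,  102106 101103 106108 101101 108108
ind0003 ,  108102 101101 101108 107106 106108
ind0004 ,  102102 104104 101106 104104 104106
ind0005 ,  102106 103103 107108 106106 106101
ind0006 ,  102102 101105 101104 106104 108106
ind0007 ,  102102 101103 103102 101101 104108
ind0008 ,  108108 101104 101103 101106 108106
ind0009 ,  102108 101101 108102 105102 101104
ind0010 ,  108108 101104 108106 101106 106104
ind0011 ,  106108 101104 106108 105102 104104
ind0012 ,  108102 101103 108104 101106 108106
ind0013 ,  102108 103101 108103 101106 108101
ind0014 ,  102102 101101 108106 105102 106108
ind0015 ,  106102 101101 106101 107106 101104
ind0016 ,  102102 101103 106108 106103 108106
ind0017 ,  106102 101103 102102 104104 106108
ind0018 ,  108102 101104 108106 104104 108108
ind0019 ,  108102 104103 108108 104103 108104
ind0020 ,  108102 105104 106103 103104 104104
ind0021 ,  108108 101101 106108 108104 108106
ind0022 ,  102108 104101 108108 108101 106101
ind0023 ,  108102 103101 106108 106101 104104
ind0024 ,  108108 103105 108108 106102 106106
Pop
ind0025 ,  108106 102101 108108 101102 106104
ind0026 ,  102108 105101 107104 104106 106106
ind0027 ,  108108 103101 108108 102105 108104
ind0028 ,  108108 103104 108108 106104 106108
ind0029 ,  102108 105103 108106 106104 106104
ind0030 ,  108102 101105 108108 103105 104101
ind0031 ,  108104 101103 104106 104101 106104
ind0032 ,  108102 101101 105103 102106 105106
ind0033 ,  102102 103101 103108 105101 105104
ind0034 ,  102102 101104 101108 104102 104106
ind0035 ,  102106 103104 102108 106102 105104
ind0036 ,  102102 103103 104108 106102 108105
ind0037 ,  108102 105105 106108 103101 106105
ind0038 ,  102108 101103 106101 106101 106104
ind0039 ,  108108 102101 102108 102104 105104
ind0040 ,  102102 104101 108103 106101 108104
ind0041 ,  102102 104101 104106 106103 108104
ind0042 ,  106102 104104 103108 102104 106108
ind0043 ,  108102 101101 106102 101106 101104
ind0044 ,  102102 103101 106102 101102 108108
ind0045 ,  102104 101103 104108 104104 108108
ind0046 ,  108102 105103 102102 104104 104106
ind0047 ,  102108 102103 108105 106106 108108
ind0048 ,  108102 104103 101108 103106 108108
Pop
ind0049 ,  106106 101101 108102 103102 108106
ind0050 ,  108108 101104 104105 102101 108108
ind0051 ,  106102 101106 101101 101106 106105
ind0052 ,  102102 101104 101102 106104 108106
ind0053 ,  108108 103104 106107 102106 106108
ind0054 ,  108107 101101 106101 102106 106108
ind0055 ,  108102 103101 105108 104103 108102
ind0056 ,  106108 103101 106103 101106 108104
ind0057 ,  102102 101108 101104 106103 104108
ind0058 ,  108106 103102 104108 106106 104104
ind0059 ,  108108 101103 101106 101101 108108
ind0060 ,  108108 101104 102102 106101 106108
ind0061 ,  102108 108102 101105 103101 106104
ind0062 ,  106108 108104 106107 101106 108108
ind0063 ,  106106 101101 101106 106101 106108
ind0064 ,  106102 101101 102107 102106 102108
ind0065 ,  102102 101101 102101 101106 106106
ind0066 ,  106108 101103 102101 102103 106108
ind0067 ,  108102 104103 104101 106103 106108
ind0068 ,  108102 101108 106106 101102 106108
ind0069 ,  102102 101101 102101 106106 108104
ind0070 ,  102108 104101 102106 106102 106106
ind0071 ,  108108 101102 105104 103106 106104
ind0072 ,  106102 103101 107107 106106 108108
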