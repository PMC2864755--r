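aa_type	chi1	chi2	chi3	chi4
S	-60	NA	NA	NA
S	60	NA	NA	NA
S	180	NA	NA	NA
V	-60	NA	NA	NA
V	60	NA	NA	NA
V	180	NA	NA	NA
L	-60	-60	NA	NA
L	60	-60	NA	NA
L	180	-60	NA	NA
L	-60	60	NA	NA
L	60	60	NA	NA
L	180	60	NA	NA
L	-60	180	NA	NA
L	60	180	NA	NA
L	180	180	NA	NA
F	-60	-60	NA	NA
F	60	-60	NA	NA
F	180	-60	NA	NA
F	-60	60	NA	NA
F	60	60	NA	NA
F	180	60	NA	NA
F	-60	180	NA	NA
F	60	180	NA	NA
F	180	180	NA	NA
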