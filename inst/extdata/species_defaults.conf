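# Default energetic parameter sets for the two emulated species.
#
# hare-like: rate coefficients calibrated so a 1.35 kg individual in the
# thermoneutral zone balances at 10.54 h/day, spends 754.3 kJ/day at
# balance, and gains 43.08 kJ per marginal active hour.
#
# porcupine-like: configuration, not ground truth -- scale-plausible
# placeholder values for an 8 kg winter-acclimatized den-using herbivore
# that subsidizes 10% of daily maintenance (398 M^0.75 kJ) from fat.

[hare-like]
I0 = 57.14171
A = 2.50590
RMR0 = 15.10510
C0 = 0.8
TLC = -5
Q = 0
fat_fraction = 0
maint_coeff = 398
b = 0.75

[porcupine-like]
I0 = 41
A = 2
RMR0 = 8
C0 = 1
TLC = -15
Q = 0.8
fat_fraction = 0.10
maint_coeff = 398
b = 0.75
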