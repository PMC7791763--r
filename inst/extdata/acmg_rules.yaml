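# ACMG-AMP evidence combining rules.
#
# Each class lists alternative minimal evidence requirements; a requirement is
# met when the evidence set contains at least the stated number of codes of
# each kind. Keys are either a single code (PVS1, BA1) or a code family
# counted by prefix (PS = PS1..PS4, PM = PM1..PM6, PP = PP1..PP5,
# BS = BS1..BS4, BP = BP1..BP7). Classes are tested in the order
# P, LP, B, LB; evidence satisfying both a pathogenic-side and a benign-side
# class is conflicting and resolves to VUS.
P:
  - {PVS1: 1, PS: 1}
  - {PVS1: 1, PM: 2}
  - {PVS1: 1, PM: 1, PP: 1}
  - {PVS1: 1, PP: 2}
  - {PS: 2}
  - {PS: 1, PM: 3}
  - {PS: 1, PM: 2, PP: 2}
  - {PS: 1, PM: 1, PP: 4}
LP:
  - {PVS1: 1, PM: 1}
  - {PS: 1, PM: 1}
  - {PS: 1, PP: 2}
  - {PM: 3}
  - {PM: 2, PP: 2}
  - {PM: 1, PP: 4}
B:
  - {BA1: 1}
  - {BS: 2}
LB:
  - {BS: 1, BP: 1}
  - {BP: 2}
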