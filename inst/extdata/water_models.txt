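# Reference table of rigid 3-site water models used for recognition.
# Values are the published model parameters:
#   TIP3P:  Jorgensen et al., J. Chem. Phys. 79, 926 (1983)
#   SPCE (SPC/E): Berendsen, Grigera & Straatsma, J. Phys. Chem. 91, 6269 (1987)
# Columns: model  q_O(e)  q_H(e)  sigma_O(nm)  epsilon_O(kJ/mol)
# version: 1
TIP3P  -0.834   0.417   0.315061  0.636386
SPCE   -0.8476  0.4238  0.316557  0.649775
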