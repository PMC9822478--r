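# Default physico-chemical descriptor list (OpenBabel / ChemmineR).
# This file is configuration: edit or replace it to change the feature set
# without touching code. Names must be drawn from available_descriptors().
- MW
- logP
- TPSA
- MR
- HBA1
- HBA2
- HBD
- nF
- natoms
- nrings
- naromrings
- nC
- nN
- nO
- nS
- nP
- nCl
- nBr
- nI
- RNH2
- R2NH
- R3N
- ROPO3
- ROH
- RCHO
- RCOR
- RCOOH
- RCOOR
- ROR
- RCCH
- RCN
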