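# Sample protein specification rules (thirteen premises, R1-R13).
# ASCII connectives: ~ negation, & conjunction, | disjunction, -> implication.
# All term names are variables, implicitly universally quantified; Px, Py
# range over proteins and Ly over ligands.
#
# Transcription note: the printed form of R12 has a conjunction symbol
# between NCBND's two arguments; NCBND takes (protein, protein), so the
# argument separator is restored as a comma.
R1: FD(Px) -> (ST(Px) -> F(Px))
R2: AAS(Px) -> ST(Px)
R3: AAS(Px) -> F(Px)
R4: CBND(Px, Ly) | AAS(Px) -> ST(Px)
R5: (FD(Px) | ST(Px)) -> F(Px)
R6: PPI(Px, Py) -> PCF(Px, Py)
R7: PCF(Px, Py) -> (F(Px) -> F(Py))
R8: PCF(Px, Py) -> F(Px) | F(Py)
R9: (ST(Px) & ST(Py)) -> (F(Px) -> F(Py))
R10: (AAS(Px) & AAS(Py)) -> (ST(Px) -> F(Py))
R11: CBND(Px, Ly) & F(Px) -> AAS(Px)
R12: NCBND(Px, Py) -> PPI(Px, Py)
R13: ST(Px) -> AAS(Px)
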