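# Known-peptaibol comparison database. Each entry is the comparison compound
# named in the relation columns of the packaged compound tables. Except for
# trikoningin KA V (whose full literature sequence is known), the sequences
# are reconstructed at isobaric-class resolution from the printed per-position
# exchange records (database token at position i = exchange source token;
# every other position = the query's token); where several rows cite the same
# entry, the mutually consistent majority reconstruction is used. This file
# is a curated fixture, not a copy of any external database. The trichorzin
# entry is a synthetic 18-residue class sequence (the cited group lacks the
# Gln/Glu at position 18) included to exercise different-length handling.
name	sequence	source_ref
Trikoningin KA V	Ac-Aib-Gly-Ala-Aib-Ile-Gln-Aib-Aib-Aib-Ser-Leu-Aib-Pro-Val-Aib-Ile-Gln-Gln-Leuol	literature sequence
Tricholongin LBII	Ac-Aib-Gly-Phe-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	reconstructed from comparison rows
Tricholongin LBIV	Ac-Aib-Gly-Phe-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	reconstructed from comparison rows
Tricholongin BII	Ac-Aib-Gly-Phe-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	reconstructed from comparison rows
Tricholongin LBIII	Ac-Aib-Gly-Phe-Aib-Aib-Gln-Aib-Aib-Aib-Ala-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	reconstructed from comparison rows
Trichostrigocin TSG-A	Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	reconstructed from comparison rows
Trichostrigocin TSG-B	Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Lxxol	reconstructed from comparison rows
Trichorzianin TA IIIb	Ac-Aib-Ala-Ala-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Gln-Trpol	reconstructed from comparison rows
Trichorzianin TA IIIc	Ac-Aib-Ala-Ala-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Gln-Trpol	reconstructed from comparison rows
Trichorzianin TA IVb	Ac-Aib-Ala-Ala-Aib-Vxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Gln-Trpol	reconstructed from comparison rows
Trichorzianin TA VIb	Ac-Aib-Ala-Ala-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Gln-Pheol	reconstructed from comparison rows
Trichorzianin TA VII	Ac-Aib-Ala-Ala-Aib-Vxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Gln-Pheol	reconstructed from comparison rows
Trichorzianin TAP-14a	Ac-Aib-Ala-Ala-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Gln-Pheol	reconstructed from comparison rows
Trichorzianin TAP-14b	Ac-Aib-Ala-Ala-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Vxx-Gln-Gln-Pheol	reconstructed from comparison rows (majority over three citing rows)
Trichorzianin TB IIIc	Ac-Aib-Ala-Ala-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Glu-Trpol	reconstructed from comparison rows
Trichorzianin TB IVb	Ac-Aib-Ala-Ala-Aib-Vxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Glu-Trpol	reconstructed from comparison rows
Trichorzianin TB VIb	Ac-Aib-Ala-Ala-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Glu-Pheol	reconstructed from comparison rows
Trichorzianin TB VII	Ac-Aib-Ala-Ala-Aib-Vxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Glu-Pheol	reconstructed from comparison rows
Trichorzin HA (synthetic)	Ac-Aib-Ala-Ala-Aib-Aib-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Gln-Lxxol	synthetic 18-residue class stand-in
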