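protein_id	qs_group
QSP_0001	Autoinducer
QSP_0002	Autoinducer
QSP_0003	Autoinducer_producer
QSP_0004	Autoinducer_producer
QSP_0005	Autoinducer_producer
QSP_0006	Autoinducer_receptor
QSP_0007	Autoinducer_receptor
QSP_0008	Autoinducer_receptor
QSP_0009	Decomposer
QSP_0010	Decomposer
QSP_0011	Decomposer
QSP_0012	Effector
QSP_0013	Effector
QSP_0014	Effector
QSP_0015	Regulator
QSP_0016	Regulator
QSP_0017	Regulator
QSP_0018	Regulator
QSP_0019	Transporter
QSP_0020	Transporter
QSP_0021	Transporter
QSP_0022	unclear
QSP_0023	unclear
QSP_0024	unclear
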