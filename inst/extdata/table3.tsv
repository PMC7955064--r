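group	vector	nll	kd_molar
ML	WRLVVSSGRRAPRGRPH	9.01	5.7e-07
ML	WRLVVSSGVRVPSGPPH	9.03	1.9e-06
ML	WRLVVSSGRRVPYGRPH	9.04	9.6e-08
ML	WALVVSSGSLVPRGPPH	9.06	9.9e-08
ML	WRLVVNSGRRVPLGRPH	9.09	5.6e-08
ML	WRLVVNSGSRAPRGLPH	9.23	7.2e-07
ML	WRLVVNSGSLVPRGSPH	9.24	6.6e-08
ML	WRLVVDSGVRVPSGRPH	9.27	4.2e-08
ML	WRLVVSSGSLAPIGTPH	9.30	4.6e-07
ML	WVLVVNSGSLVPSSPPH	9.30	8.7e-08
Freq	SVRTVLLGHDSPHIRPH	28.00	4.3e-06
Freq	WNVAISLSAHSAVMDAH	23.00	3.9e-06
Freq	DLTRVTQGEVVPRLRPH	22.00	3.7e-07
Freq	WLSSVAHSTVAPRPPAR	20.00	4.4e-06
Freq	WNTYLVSGKMVPIRLPH	13.00	3.0e-06
Freq	RWSIVVSGWLVPGGNPH	13.00	9.2e-07
Freq	WSSWLGMSALVADRSPH	13.00	1.9e-06
Freq	NSIAISAGLYVPSGSAH	13.00	2.8e-07
Freq	WSYSLLHGVGVPDGLPH	12.00	5.9e-06
Freq	HHMSVRSGAQSPFFRAH	12.00	1.5e-05
Control	TSAGIIFGTNAPVARPR	NA	7.7e-05
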