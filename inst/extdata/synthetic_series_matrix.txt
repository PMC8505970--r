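!Series_title	"Synthetic miniature series-matrix fixture (hand-written, not derived from any GEO record)"
!Sample_title	"patient_1"	"patient_2"	"patient_3"	"patient_4"
!Sample_geo_accession	"SYN001"	"SYN002"	"SYN003"	"SYN004"
!Sample_characteristics_ch1	"response: responder"	"response: responder"	"response: non_responder"	"response: non_responder"
!series_matrix_table_begin
"ID_REF"	"SYN001"	"SYN002"	"SYN003"	"SYN004"
"IL6"	5.10	4.90	7.25	7.40
"MME"	6.05	5.80	8.10	7.95
"PTGS2"	4.20	4.35	6.50	6.10
"ADH1C"	9.10	8.95	7.20	7.05
"C10orf99"	8.40	8.60	6.30	6.45
!series_matrix_table_end
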