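chr2	rbpsplice_fix	exon	1001	1200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "1";
chr2	rbpsplice_fix	exon	1501	1700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "2";
chr2	rbpsplice_fix	exon	2001	2200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "3";
chr2	rbpsplice_fix	exon	2501	2700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "4";
chr2	rbpsplice_fix	exon	3001	3200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "5";
chr2	rbpsplice_fix	exon	3501	3700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "6";
chr2	rbpsplice_fix	exon	4001	4200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "7";
chr2	rbpsplice_fix	exon	4501	4700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "8";
chr2	rbpsplice_fix	exon	5001	5200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "9";
chr2	rbpsplice_fix	exon	5501	5700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "10";
chr2	rbpsplice_fix	exon	6001	6200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "11";
chr2	rbpsplice_fix	exon	6501	6700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "12";
chr2	rbpsplice_fix	exon	7001	7200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "13";
chr2	rbpsplice_fix	exon	7501	7700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "14";
chr2	rbpsplice_fix	exon	8001	8200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.GAC"; exon_number "15";
chr2	rbpsplice_fix	exon	1001	1200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "1";
chr2	rbpsplice_fix	exon	1501	1700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "2";
chr2	rbpsplice_fix	exon	2001	2200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "3";
chr2	rbpsplice_fix	exon	2501	2700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "4";
chr2	rbpsplice_fix	exon	3001	3200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "5";
chr2	rbpsplice_fix	exon	3501	3700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "6";
chr2	rbpsplice_fix	exon	4001	4200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "7";
chr2	rbpsplice_fix	exon	4501	4700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "8";
chr2	rbpsplice_fix	exon	5001	5200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "9";
chr2	rbpsplice_fix	exon	5501	5700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "10";
chr2	rbpsplice_fix	exon	6001	6200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "11";
chr2	rbpsplice_fix	exon	6501	6700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "12";
chr2	rbpsplice_fix	exon	7001	7200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "13";
chr2	rbpsplice_fix	exon	7501	7700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "14";
chr2	rbpsplice_fix	exon	8501	8700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "15";
chr2	rbpsplice_fix	exon	9001	9200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "16";
chr2	rbpsplice_fix	exon	9501	9700	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "17";
chr2	rbpsplice_fix	exon	10001	10200	.	+	.	gene_id "GLSL"; transcript_id "GLSL.KGA"; exon_number "18";
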