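##fileformat=VCFv4.2
##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">
##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">
##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">
##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQ rank sum">
##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	tea01	tea02	tea03
chr1	1201	.	A	G	228.4	.	QD=25.1;FS=0.53;MQ=58.9;MQRankSum=0.31;ReadPosRankSum=-0.44	GT:DP	0/1:15	0/0:12	1/1:17
chr1	1209	.	T	C	39.2	.	QD=1.7;FS=2.10;MQ=55.0	GT:DP	0/0:11	0/1:9	./.:.
chr1	2330	.	CTT	C	310.0	.	QD=21.0;FS=1.00;MQ=57.2	GT:DP	0/1:14	0/1:13	0/0:15
chr1	2333	.	G	A	96.7	.	QD=12.4;FS=0.80;MQ=59.1;MQRankSum=-0.12;ReadPosRankSum=0.25	GT:DP	0/0:13	0/1:16	0/1:12
chr1	5120	.	C	T,A	152.3	.	QD=9.8;FS=3.40;MQ=51.6	GT:DP	1/2:18	0/1:14	0/0:10
chr1	8844	.	G	T	67.5	.	QD=8.2;FS=61.2;MQ=44.0;MQRankSum=-1.90;ReadPosRankSum=-0.70	GT:DP	0/0:9	0/0:10	0/1:11
chr2	410	.	A	C	410.9	.	QD=29.3;FS=0.00;MQ=60.0;MQRankSum=0.00;ReadPosRankSum=0.10	GT:DP	1/1:21	0/1:19	0/1:23
chr2	3975	.	T	G	88.8	.	QD=14.6;FS=5.70;MQ=52.4;MQRankSum=-11.00;ReadPosRankSum=-7.90	GT:DP	0/1:12	./.:.	0/0:14
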