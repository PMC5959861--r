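component	CNT-opsin	CNT-hOR2AG1	CNT-icaridin	Free-icaridin	CNT-3-nonanone	Free-3-nonanone	CNT-2-pentanol	Free-2-pentanol
ele	-0.0	-0.0	-9.5	-1.6	-0.5	0.4	-2.9	-2.3
vdw	-176.8	-182.0	-36.7	-27.4	-22.1	-19.3	-15.0	-13.1
gas	-176.8	-182.0	-46.2	-29.0	-22.6	-18.9	-17.9	-15.4
npsolv	-6.5	-7.9	-4.5	-3.6	-3.7	-2.8	-2.4	-2.2
psolv	61.6	74.1	14.5	12.6	7.1	6.9	8.1	7.4
solv	55.1	66.2	10.0	8.9	3.4	4.1	5.7	5.2
binding	-121.7	-115.8	-26.1	-20.1	-19.2	-14.7	-12.1	-10.2
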