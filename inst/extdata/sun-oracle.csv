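time_utc,elevation_deg,azimuth_deg
2012-10-05T05:13:00Z,7.1885,95.2302
2012-10-23T10:36:00Z,75.9906,176.7493
2012-11-12T15:59:00Z,8.8021,251.4577
2012-12-04T08:22:00Z,47.2202,127.1518
2012-12-17T13:45:00Z,40.5150,236.1037
2013-01-01T07:08:00Z,28.4506,117.8264
2013-01-18T11:31:00Z,66.3350,195.0765
2013-02-06T16:54:00Z,2.9875,254.4230
2013-02-27T09:17:00Z,60.4588,111.2864
2013-03-11T14:40:00Z,35.9257,263.9574
2013-03-25T08:03:00Z,45.5537,89.6674
2013-04-10T12:26:00Z,66.9255,285.2855
2013-04-28T05:49:00Z,14.2856,75.9357
2013-05-18T11:12:00Z,72.0057,344.0920
2013-06-09T15:35:00Z,19.1408,293.5301
2013-06-22T08:58:00Z,54.3351,51.3147
2013-07-07T13:21:00Z,50.2897,303.3932
2013-07-24T06:44:00Z,24.8792,69.2190
2013-08-12T12:07:00Z,69.2892,307.9551
2013-09-02T16:30:00Z,6.3801,277.4696
2013-09-14T09:53:00Z,75.6246,86.0496
2013-09-28T14:16:00Z,37.1843,265.3972
2013-10-14T07:39:00Z,43.4218,103.6873
2013-11-01T13:02:00Z,50.6392,243.4049
2013-11-21T05:25:00Z,9.5569,110.6827
2013-12-13T10:48:00Z,64.4617,179.3759
2013-12-26T16:11:00Z,9.2831,245.8862
2014-01-10T08:34:00Z,46.3655,125.8301
2014-01-27T13:57:00Z,43.4685,241.7024
2014-02-15T06:20:00Z,16.7291,104.0014
2014-03-08T11:43:00Z,78.2439,232.3592
2014-03-20T17:06:00Z,-0.9075,270.0416
2014-04-03T09:29:00Z,67.5384,81.7098
2014-04-19T14:52:00Z,30.3689,281.7002
2014-05-07T07:15:00Z,34.9193,71.0787
2014-05-27T12:38:00Z,58.0030,308.3889
2014-06-18T06:01:00Z,15.8420,66.3293
2014-07-01T10:24:00Z,67.6240,21.4251
2014-07-16T15:47:00Z,18.0873,291.6512
2014-08-02T09:10:00Z,58.6903,58.7518
2014-08-21T13:33:00Z,50.4367,286.0961
2014-09-11T06:56:00Z,31.1684,86.1025
2014-09-23T11:19:00Z,81.6950,252.5249
2014-10-07T16:42:00Z,-0.0551,264.3460
2014-10-23T10:05:00Z,73.7726,148.4898
2014-11-10T14:28:00Z,30.2342,248.4638
2014-11-30T07:51:00Z,41.4975,121.9662
2014-12-22T12:14:00Z,57.5972,216.1041
2015-01-04T05:37:00Z,7.6761,113.3348
2015-01-19T11:00:00Z,67.2435,176.6304
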